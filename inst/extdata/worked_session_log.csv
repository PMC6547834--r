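subject_id,session,task_id,time_s,dnf,quadrant
S01,1,lifting_light_object,15.6,0,1
S01,1,rotate_screw,NA,1,1
S01,1,door_handle,10.399999999999999,0,2
S01,1,open_close_zip,28.6,0,2
S01,2,lifting_light_object,11.4,0,3
S01,2,rotate_screw,19,0,3
S01,2,door_handle,7.6,0,3
S01,2,open_close_zip,20.900000000000002,0,3
S01,3,lifting_light_object,9.3,0,1
S01,3,rotate_screw,15.5,0,2
S01,3,door_handle,6.200000000000001,0,1
S01,3,open_close_zip,17.05,0,2
S02,1,lifting_light_object,13.5,0,4
S02,1,rotate_screw,22.5,0,4
S02,1,door_handle,9,0,4
S02,1,open_close_zip,24.75,0,1
S02,2,lifting_light_object,9.3,0,2
S02,2,rotate_screw,15.5,0,2
S02,2,door_handle,6.200000000000001,0,2
S02,2,open_close_zip,17.05,0,2
S02,3,lifting_light_object,7.199999999999999,0,1
S02,3,rotate_screw,12,0,3
S02,3,door_handle,4.799999999999999,0,3
S02,3,open_close_zip,13.2,0,4
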