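subject_id,session,trial,blocks
S01,2,1,20
S01,2,2,22
S01,2,3,24
S01,3,1,30
S01,3,2,30
S01,3,3,30
S02,2,1,25
S02,2,2,26
S02,2,3,27
S02,3,1,33
S02,3,2,35
S02,3,3,34
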