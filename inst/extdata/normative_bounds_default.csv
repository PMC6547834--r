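task_id,n_lower_s,m_upper_s
light_spherical,2.5,20
light_tripod,2.2,17.6
light_power,2.0,16
light_lateral,2.4,19.2
light_tip,2.8,22.4
light_extension,2.6,20.8
heavy_spherical,3.0,24
heavy_tripod,2.7,21.6
heavy_power,2.5,20
heavy_lateral,2.9,23.2
heavy_tip,3.3,26.4
heavy_extension,3.1,24.8
lifting_light_object,3.0,24
lifting_heavy_object,3.5,28
rotate_key,3.2,25.6
rotate_screw,5.0,40
door_handle,2.0,16
open_close_zip,5.5,44
glass_jug_pouring,8.0,64
page_turning,4.0,32
carton_pouring,9.0,72
button_board,12.0,96
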