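task_id,pattern
light_spherical,spherical
heavy_spherical,spherical
lifting_light_object,spherical
light_tripod,tripod
heavy_tripod,tripod
rotate_screw,tripod
light_power,power
heavy_power,power
lifting_heavy_object,power
door_handle,power
glass_jug_pouring,power
carton_pouring,power
light_lateral,lateral
heavy_lateral,lateral
rotate_key,lateral
open_close_zip,lateral
page_turning,lateral
light_tip,tip
heavy_tip,tip
open_close_zip,tip
page_turning,tip
button_board,tip
light_extension,extension
heavy_extension,extension
door_handle,extension
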