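category,measure,plateau,rate,r2,endpoint,session_offset
ts_lifting_light_object,ts,81.810,8.036,0.053,1,0
ts_rotate_key,ts,78.153,7.658,0.014,1,0
ts_heavy_power,ts,85.905,17.054,0.739,2,0
ts_heavy_lateral,ts,77.017,13.366,0.063,2,0
ts_heavy_extension,ts,73.555,14.380,0.313,2,0
ts_light_spherical,ts,85.515,16.495,0.407,2,0
ts_light_lateral,ts,80.019,9.191,0.073,2,0
ts_heavy_spherical,ts,77.226,12.991,0.005,2,0
ts_heavy_tripod,ts,68.066,15.068,0.144,3,0
ts_heavy_tip,ts,72.624,20.719,0.185,3,0
ts_rotate_screw,ts,68.910,13.875,0.040,3,0
ts_door_handle,ts,93.587,22.090,0.940,3,0
ts_open_close_zip,ts,81.115,19.785,0.307,3,0
ts_light_power,ts,89.998,32.045,0.934,4,0
ts_lifting_heavy_object,ts,91.678,30.437,0.906,4,0
ts_glass_jug_pouring,ts,74.551,25.199,0.589,4,0
ts_page_turning,ts,84.145,28.916,0.574,4,0
ts_light_tripod,ts,77.954,31.493,0.527,5,0
ts_light_extension,ts,78.645,36.015,0.681,5,0
ts_carton_pouring,ts,79.164,34.153,0.602,5,0
ts_button_board,ts,80.999,38.876,0.826,5,0
ts_light_tip,ts,72.735,37.968,0.621,6,0
lif_lateral,lif,78.171,15.040,0.691,2,0
lif_spherical,lif,80.635,21.213,0.493,3,0
lif_power,lif,85.315,20.590,0.823,3,0
lif_tripod,lif,75.673,28.479,0.818,4,0
lif_tip,lif,77.125,25.001,0.885,4,0
lif_extension,lif,78.782,26.437,0.806,4,0
wlif,wlif,79.75,22.09,0.94,3,0
bbt,bbt,37.21,15.91,0.64,6,1
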