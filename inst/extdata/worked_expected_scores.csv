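subject_id,session,lif_extension,lif_lateral,lif_power,lif_spherical,lif_tip,lif_tripod,wlif,n_dnf,bbt_mean
S01,1,40.00000000000001,39.99999999999999,40.00000000000001,40,39.99999999999999,0,35.2,1,NA
S01,2,60,60,60,60,60,60,60,0,22
S01,3,69.99999999999999,70,69.99999999999999,70,70,70,70,0,30
S02,1,50,50,50,50,50,50,50,0,NA
S02,2,69.99999999999999,70,69.99999999999999,70,70,70,70,0,26
S02,3,80,80,80,80,80,80,80,0,34
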