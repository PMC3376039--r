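patient_id,side,slice_index,kidney_area_cm2,cortex_area_cm2,spacing_cm
P0001,left,1,8.2,3.1,0.5
P0001,left,2,14.6,5.9,0.5
P0001,left,3,16.9,6.8,0.5
P0001,left,4,15.1,6.0,0.5
P0001,left,5,9.0,3.4,0.5
P0001,right,1,7.9,3.0,0.5
P0001,right,2,13.8,5.5,0.5
P0001,right,3,16.0,6.3,0.5
P0001,right,4,14.2,5.6,0.5
P0001,right,5,8.4,3.2,0.5
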