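patient_id,section_id,cortex_segment_lengths,n_glomeruli,n_global_sclerosis,needle_gauge,stain
P0001,1,5.2;3.1,12,1,16,PAS
P0001,2,7.4,9,0,16,PAS
P0001,3,2.0,1,0,16,PAS
P0002,1,6.8,5,2,18,PAM-HE
P0002,2,4.1;1.2,4,0,18,PAM-HE
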