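patient_id,biopsy_date,age,sex,serum_creatinine,birth_weight_g,body_weight_kg,us_major_axis_cm,us_minor_axis_cm,us_transverse_axis_cm,biopsied_side,diagnosis
P0001,2011-03-15,52,male,1.10,3100,68.5,10.8,4.6,5.1,left,IgA nephropathy
P0002,2011-05-02,34,female,0.95,2350,51.2,10.1,4.2,4.8,right,minimal change disease
P0003,2011-06-20,61,male,1.45,,74.0,11.2,4.9,5.3,left,nephrosclerosis
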