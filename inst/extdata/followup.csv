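patient_id,visit_date,serum_creatinine,body_weight_kg,urinary_protein_gday,raas_blocker,status,event_type,event_date,chest_symptoms,ecg_changes,elevated_enzymes,ecg_abnormalities,intervention_needed,symptoms_over_24h,lesion_on_imaging,is_tia_or_asymptomatic
P0001,2012-03-10,1.25,68.0,0.45,yes,followed,,,,,,,,,,
P0001,2013-05-11,1.60,67.2,0.80,yes,followed,,,,,,,,,,
P0001,2014-03-18,2.95,66.0,1.20,yes,followed,,,,,,,,,,
P0002,2012-05-01,0.98,51.0,0.20,no,followed,,,,,,,,,,
P0002,2013-04-28,1.01,50.6,0.25,no,followed,mi,2013-02-14,TRUE,FALSE,TRUE,,,,,
P0003,2012-06-25,1.50,73.1,0.60,yes,followed,,,,,,,,,,
P0003,2013-06-18,1.52,73.5,0.55,yes,lost,,,,,,,,,,
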