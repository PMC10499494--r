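record_id,ivsd_cm,lvidd_cm,pwtd_cm,height_cm,weight_kg,sex
synthA,1.0,5.0,1.0,170,70,male
synthB,1.3,5.6,1.2,182,95,male
synthC,0.8,4.4,0.8,158,54,female
synthD,1.4,5.9,1.3,168,88,female
synthE,0.9,4.9,0.9,176,72,male
synthF,1.1,5.2,1.1,163,70,female
synthG,1.5,6.1,1.4,171,90,male
synthH,0.7,4.2,0.7,155,48,female
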