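study,n_individuals,dose_mg,fasted,body_weight_kg,vmax_liv,renal_clearance_ena,renal_clearance_enaat,ace_c_ref,v_liver_L
biollaz,12,10,TRUE,70.0,184.87,6.02e-3,2.99e-4,2.59,1.56
gu,20,10,FALSE,70.0,178.18,4.51e-3,8.01e-4,1.86,1.57
lee,12,20,FALSE,70.0,131.88,6.53e-3,4.99e-4,4.32,1.57
lu,20,10,TRUE,70.0,148.05,5.02e-3,6.30e-4,1.30,1.35
najib,24,20,TRUE,73.38,146.50,4.61e-3,6.37e-4,2.14,1.49
noormohamed,12,20,TRUE,70.0,194.36,5.50e-3,6.21e-4,4.15,1.42
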