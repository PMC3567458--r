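organ,plasma_volume_L,blood_flow_L_per_min,ace_expression_pct,at1_expression_pct
arterial_blood,0.500,6.593,0,0
venous_blood,1.000,6.593,0,0
brain,0.055,0.700,15,5
fat,0.100,0.300,6,0
gonads,0.002,0.003,2,4
heart,0.020,0.240,0,9
kidney,0.050,1.100,0,100
large_intestine,0.040,0.250,2,27
liver,0.300,1.500,0,76
lung,0.300,6.593,100,6
muscle,0.350,1.000,0,8
pancreas,0.010,0.060,0,0
plasma,0.100,0.300,6,0
skin,0.080,0.300,0,57
spleen,0.030,0.180,0,89
small_intestine,0.060,0.600,1,27
stomach,0.010,0.060,3,0
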