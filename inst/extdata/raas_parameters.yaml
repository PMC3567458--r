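# Default kinetic and physiological parameters of the circulating RAAS model.
# Concentrations in umol/L, times in min, volumes in L, rate constants as noted.
# reference_plasma_conc = pre-administration steady-state venous concentration.
agt:
  molecular_weight_kda: 53.15
  reference_plasma_conc: 0.60
  t_half: 11.29                # min
  k_secretion: 7.81            # L/min, hepatic secretion
renin:
  molecular_weight_kda: 48.0
  reference_plasma_conc: 3.62e-07
  kcat: 3.60                   # 1/min, AGT -> Ang1
  km: 5.04e-02                 # umol/L
  t_half: 1.44
ace:
  molecular_weight_kda: 180.0
  k_on: 35.16                  # L/umol/min, enalaprilat association
  k_off: 2.15e-02              # 1/min, enalaprilat dissociation
  kcat: 4.48e-04               # 1/min, Ang1 -> Ang2
  km: 4.12e-03                 # umol/L
ang1:
  molecular_weight_kda: 1.30
  reference_plasma_conc: 7.91e-06
  t_half: 0.72
ang2:
  molecular_weight_kda: 1.05
  reference_plasma_conc: 4.84e-06
  log_p: -1.7
  k_inhibition: 1.87e-08       # umol/L, feedback on prorenin activation
  t_half: 1.54
at1:
  molecular_weight_kda: 41.0
  c_ref: 7.69                  # umol/L, reference receptor concentration
  k_on: 23.50                  # L/umol/min, Ang2 association
  k_off: 3.07e-02              # 1/min
aldosterone:
  molecular_weight_kda: 0.36
  reference_plasma_conc: 2.07e-04
  log_p: 1.08
  protein_binding_pct: 50
  k_production: 1.51e-06       # umol/min, basal zero-order synthesis
  k_secretion: 7.81            # L/min, complex-driven synthesis
  t_half: 12.87
prorenin:
  molecular_weight_kda: 57.0
  reference_plasma_conc: 1.21e-06
  c_cell_ref: 1.1e-04          # umol/L, renal intracellular reference
  vmax_kid: 1.62               # umol/min/L, activation Vmax
  km_kid: 4.68e-02             # umol/L
  k_secretion: 4.68e-02        # L/min
  v_kidney: 0.24               # L, intracellular kidney volume
  t_half: 5.07
carboxylesterase:
  km_liv: 710.0                # umol/L, hepatic Ena -> Enaat
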