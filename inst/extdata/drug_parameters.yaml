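# Physicochemical and clearance properties of enalapril (Ena) and
# enalaprilat (Enaat). Renal clearances used in simulations are the
# study-specific per-kg values (see studies.csv); the whole-body values here
# are retained as metadata only. k_org: tissue:plasma partition coefficient.
ena:
  molecular_weight_g_mol: 376.5
  log_p: 0.07
  pka: [3.74, 4.75]
  plasma_protein_binding_pct: 50
  hepatic_clearance_ml_min: 354
  renal_clearance_l_h: 18        # metadata; simulations use per-kg study values
  k_org: 1.0
enaat:
  molecular_weight_g_mol: 348.4
  log_p: -0.74
  pka: [2.03, 4.03]
  plasma_protein_binding_pct: 50
  renal_clearance_l_h: 8.75      # metadata (printed range 8-9.5)
  k_org: 1.0
absorption:
  ka: 0.03                       # 1/min, first-order gut depot emptying
  f_abs: 0.6                     # fraction of dose reaching liver plasma
permeation:
  ps_liver: 1.0                  # L/min, liver plasma <-> hepatocyte exchange
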