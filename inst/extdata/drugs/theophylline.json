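{
  "name": "theophylline",
  "mw_g_mol": 180.2,
  "log_p": -0.02,
  "compound_type": "ampholyte",
  "pka1": 8.8,
  "pka2": 0.99,
  "bp_ratio": 0.82,
  "fu_plasma": 0.5,
  "distribution": "minimal",
  "elimination_fractions": {"metabolism": 0.90, "renal": 0.10},
  "enzyme_fractions": {"CYP1A2": 0.75, "CYP2D6": 0.07, "CYP2E1": 0.10, "CYP3A4": 0.08},
  "clint_ul_min_pmol": {"CYP1A2": 0.02, "CYP2D6": 0.011, "CYP2E1": 0.0022, "CYP3A4": 0.00078},
  "cl_renal_adult_L_h": 0.31,
  "vss_L_kg": 0.5,
  "neonatal_overrides": {"fu_plasma": 0.62, "vss_L_kg": 0.6},
  "clint_calibration": 1.25
}
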