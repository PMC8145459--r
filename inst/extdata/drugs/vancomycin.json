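{
  "name": "vancomycin",
  "mw_g_mol": 1449.26,
  "log_p": -3.75,
  "compound_type": "ampholyte",
  "pka1": 2.18,
  "pka2": 7.75,
  "bp_ratio": 0.75,
  "fu_plasma": 0.672,
  "distribution": "full_perfusion_limited",
  "elimination_fractions": {"renal": 0.775},
  "cl_renal_adult_L_h": 6,
  "vss_L_kg": 0.445
}
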