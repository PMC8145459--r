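{
  "name": "ceftazidime",
  "mw_g_mol": 546.58,
  "log_p": -2.65,
  "compound_type": "diprotic acid",
  "pka1": 2.4,
  "pka2": 4.26,
  "bp_ratio": 0.55,
  "fu_plasma": 0.9,
  "distribution": "full_perfusion_limited",
  "elimination_fractions": {"renal": 0.73},
  "cl_renal_adult_L_h": 6,
  "vss_L_kg": 0.195
}
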