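{
  "name": "fentanyl",
  "mw_g_mol": 336.47,
  "log_p": 4.05,
  "compound_type": "base",
  "pka1": 8.99,
  "bp_ratio": 0.87,
  "fu_plasma": 0.16,
  "distribution": "full_perfusion_limited",
  "elimination_fractions": {"metabolism": 0.94, "renal": 0.06},
  "enzyme_fractions": {"CYP3A4": 1.0},
  "clint_ul_min_pmol": {"CYP3A4": 0.707},
  "cl_renal_adult_L_h": 2.232,
  "vss_L_kg": 4.071,
  "clint_calibration": 1.6
}
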