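# CN-pediatric system constants: adult hepatic CYP abundances (pmol/mg
# microsomal protein), in vivo ontogeny Hill profiles, MPPGL age
# coefficients (log10 polynomial), GFR maturation parameters and the adult
# reference anatomy used for calibration.
enzyme_abundance_adult:
  CYP1A2: 52
  CYP2D6: 8
  CYP2E1: 61
  CYP3A4: 137
ontogeny:
  CYP1A2: {f_birth: 0.28, age50_y: 0.60, hill_n: 1.2}
  CYP2D6: {f_birth: 0.10, age50_y: 0.10, hill_n: 1.0}
  CYP2E1: {f_birth: 0.10, age50_y: 0.50, hill_n: 1.0}
  CYP3A4: {f_birth: 0.25, age50_y: 0.30, hill_n: 1.0}
mppgl_coefs: [1.407, 0.0158, -0.000384, 0.0000033]
gfr:
  adult_mL_min_1p73: 121
  tm50_weeks: 47.7
  hill: 3.4
  term_pma_weeks: 40
adult_reference:
  age_y: 30
  sex: male
  weight_kg: 70
  height_cm: 170
  hematocrit_frac: 0.45
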