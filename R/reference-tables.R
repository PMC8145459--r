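# Packaged physiological reference tables.
#
# The six organs with population-specific growth equations (brain, heart,
# kidney, liver, pancreas, spleen) are computed in population.R.  Everything
# else uses the age-indexed reference tables below: fraction-of-body-weight
# tissue masses and fraction-of-cardiac-output perfusion, in the style of
# ICRP-89 reference anatomy, linearly interpolated in age.  A residual
# "rest" tissue closes the mass balance and the flow balance.

# organs with population-specific (recalibrated) equations
.recalibrated_organs <- c("brain", "heart", "kidney", "liver", "pancreas", "spleen")

# tissues taken from the reference table
.default_tissues <- c("lung", "adipose", "muscle", "skin", "bone", "gut", "blood")

# all modelled tissues of a subject (rest closes mass balance)
.all_tissues <- c(.recalibrated_organs, .default_tissues, "rest")

# printed tissue densities (g/mL); 1.0 everywhere else
.tissue_density <- c(heart = 1.04, pancreas = 1.05, spleen = 1.06)

tissue_density <- function(organ) {
  d <- .tissue_density[organ]
  d[is.na(d)] <- 1.0
  unname(d)
}

# Tissue mass as fraction of body weight, by age (years).  Linear
# interpolation between rows; constant extrapolation beyond the ends.
.tissue_mass_fraction <- data.frame(
  age_y   = c(0,     1,     5,     10,    15,    18),
  lung    = c(0.010, 0.009, 0.008, 0.0075, 0.007, 0.007),
  adipose = c(0.190, 0.220, 0.170, 0.170, 0.190, 0.210),
  muscle  = c(0.200, 0.210, 0.260, 0.300, 0.350, 0.380),
  skin    = c(0.075, 0.065, 0.055, 0.048, 0.044, 0.042),
  bone    = c(0.085, 0.090, 0.100, 0.110, 0.115, 0.120),
  gut     = c(0.022, 0.020, 0.018, 0.017, 0.016, 0.016),
  blood   = c(0.085, 0.080, 0.078, 0.076, 0.075, 0.075)
)

# Organ perfusion as fraction of cardiac output, by age.  The hepatic
# artery (ha) is listed separately from the portal organs; total liver
# perfusion is ha + gut + spleen + pancreas.  "rest" closes the sum to 1.
.flow_fraction <- data.frame(
  age_y    = c(0,     18),
  brain    = c(0.210, 0.120),
  heart    = c(0.035, 0.040),
  kidney   = c(0.160, 0.190),
  ha       = c(0.060, 0.065),
  gut      = c(0.140, 0.150),
  spleen   = c(0.025, 0.030),
  pancreas = c(0.010, 0.010),
  adipose  = c(0.035, 0.050),
  muscle   = c(0.110, 0.170),
  skin     = c(0.060, 0.050),
  bone     = c(0.040, 0.050)
)

.interp_row <- function(table, age_y) {
  cols <- setdiff(names(table), "age_y")
  age <- min(max(age_y, min(table$age_y)), max(table$age_y))
  out <- vapply(cols, function(cl) approx(table$age_y, table[[cl]], xout = age)$y,
                numeric(1))
  names(out) <- cols
  out
}

# Tissue composition for mechanistic tissue:plasma partitioning
# (Rodgers-Rowland style): fractional volumes of extracellular water (f_ew),
# intracellular water (f_iw), neutral lipid (f_nl), neutral phospholipid
# (f_np); acidic phospholipid content (ap, mg/g) and the tissue:plasma
# albumin-equivalent ratio (pr_ratio) used for acids/neutrals.
.tissue_composition <- data.frame(
  tissue   = c("adipose", "bone",  "brain", "gut",   "heart", "kidney",
               "liver",   "lung",  "muscle", "pancreas", "skin", "spleen", "rest"),
  f_ew     = c(0.135,     0.100,   0.162,   0.282,   0.320,   0.273,
               0.161,     0.336,   0.118,   0.120,   0.382,   0.207,   0.118),
  f_iw     = c(0.017,     0.346,   0.620,   0.475,   0.456,   0.483,
               0.573,     0.446,   0.630,   0.664,   0.291,   0.579,   0.630),
  f_nl     = c(0.853,     0.074,   0.039,   0.038,   0.014,   0.012,
               0.014,     0.022,   0.010,   0.041,   0.060,   0.0077,  0.010),
  f_np     = c(0.0016,    0.0017,  0.0015,  0.0125,  0.0111,  0.0240,
               0.0240,    0.0128,  0.0072,  0.0093,  0.0044,  0.0113,  0.0072),
  ap       = c(0.40,      0.67,    0.40,    2.41,    2.25,    5.03,
               4.56,      3.91,    1.53,    1.67,    1.32,    3.18,    1.53),
  pr_ratio = c(0.05,      0.10,    0.05,    0.41,    0.46,    0.41,
               0.50,      0.47,    0.64,    0.44,    0.78,    0.28,    0.64),
  stringsAsFactors = FALSE
)

# plasma and blood-cell composition used by the partitioning model
.plasma_comp <- c(f_water = 0.945, f_nl = 0.0035, f_np = 0.00225)
.bc_comp <- c(f_iw = 0.603, f_nl = 0.0017, f_np = 0.0029, ap = 0.5)
.ph <- c(plasma = 7.4, iw = 7.0, bc = 7.22)

# Haematocrit (%) and serum albumin (g/L) by observed age band and sex
# (2.5th-97.5th percentile truncation bounds included).  Below 11 years the
# national survey provides no finer granularity; constant defaults are used
# (see hematocrit_albumin_for).
.hct_alb_bands <- data.frame(
  age_lo = rep(c(11, 13, 15, 17), each = 2),
  age_hi = rep(c(13, 15, 17, 18.0001), each = 2),
  sex    = rep(c("male", "female"), times = 4),
  hct_mean = c(41.96, 41.83, 43.87, 41.95, 46.02, 41.94, 46.84, 41.73),
  hct_sd   = c(2.58,  2.47,  2.86,  2.72,  2.94,  2.68,  2.90,  2.64),
  hct_lo   = c(37.00, 37.00, 38.10, 36.39, 39.50, 36.10, 40.90, 36.20),
  hct_hi   = c(47.30, 46.50, 49.50, 47.20, 51.40, 46.80, 52.20, 46.70),
  alb_mean = c(47.86, 47.90, 48.20, 48.29, 49.25, 48.94, 49.88, 48.89),
  alb_sd   = c(2.89,  2.86,  3.21,  3.17,  3.29,  3.26,  3.11,  3.07),
  alb_lo   = c(42.77, 42.90, 42.30, 42.38, 43.48, 43.10, 44.00, 43.30),
  alb_hi   = c(54.00, 54.10, 55.00, 55.10, 56.20, 56.27, 56.56, 55.50),
  stringsAsFactors = FALSE
)
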