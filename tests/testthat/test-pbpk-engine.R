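# Tissue partitioning, Vss calibration, and the two disposition engines.

test_that("neutral low-lipophilicity unbound compounds partition like
           tissue water", {
  d <- drug_model("water_probe", 100, 0, "neutral", bp_ratio = 1,
                  fu_plasma = 1, distribution = "full_perfusion_limited",
                  vss_L_kg = 0.7)
  kp <- predict_kp(d)
  expect_true(all(kp$kp >= 0.4 & kp$kp <= 1.25))
})

test_that("Kp prediction is positive for the built-ins and reflects
           polarity", {
  for (nm in c("fentanyl", "ceftazidime", "vancomycin")) {
    kp <- predict_kp(builtin_drug(nm))
    expect_true(all(kp$kp > 0))
  }
  # polar compounds avoid fat: adipose below muscle for vancomycin
  kpv <- predict_kp(builtin_drug("vancomycin"))
  expect_lt(kpv$kp[["adipose"]], kpv$kp[["muscle"]])
  d <- drug_model("x", 100, 1, "base", bp_ratio = 1, fu_plasma = 0.5,
                  distribution = "minimal", vss_L_kg = 1)
  expect_error(predict_kp(d), "pka1")
})

test_that("lambda calibration hits the reported Vss in closed form", {
  fen <- builtin_drug("fentanyl")
  kp <- calibrate_kp_to_vss(predict_kp(fen), fen, adult)
  expect_equal(vss_of(kp, adult), 4.071, tolerance = 1e-10)
  cef <- builtin_drug("ceftazidime")
  kpc <- calibrate_kp_to_vss(predict_kp(cef), cef, adult)
  expect_equal(vss_of(kpc, adult), 0.195, tolerance = 1e-10)
  # lambda is 1 when the uncalibrated set already matches the target
  raw <- predict_kp(fen)
  fen2 <- fen; fen2$vss_L_kg <- vss_of(raw, adult)
  expect_equal(calibrate_kp_to_vss(raw, fen2, adult)$scalar_lambda, 1,
               tolerance = 1e-12)
  # a target below the blood contribution is infeasible
  fen3 <- fen; fen3$vss_L_kg <- 0.01
  expect_error(calibrate_kp_to_vss(raw, fen3, adult), "infeasible")
})

test_that("the minimal engine matches the one-compartment closed form", {
  theo <- builtin_drug("theophylline")
  s <- mean_subject(8, "male")
  V <- theo$vss_L_kg * s$weight_kg
  CL <- total_cl(theo, s)
  tt <- sort(unique(c(seq(0, 2, 0.05), seq(2, 48, 0.25))))
  # bolus: C(0+) = dose / V, then mono-exponential decay
  simb <- simulate_minimal(theo, s, dose_regimen("iv_bolus", 4), tt)
  expect_equal(simb$conc_mg_L[1], 4 * s$weight_kg / V)
  expect_equal(simb$conc_mg_L,
               4 * s$weight_kg / V * exp(-CL / V * tt), tolerance = 1e-7)
  # infusion: analytic rise and decay, Cmax exactly at end of infusion
  reg <- dose_regimen("iv_infusion", 4, infusion_min = 30)
  simi <- simulate_minimal(theo, s, reg, tt)
  k <- CL / V; R <- 4 * s$weight_kg / 0.5
  analytic <- ifelse(tt <= 0.5, R / (k * V) * (1 - exp(-k * tt)),
                     R / (k * V) * (1 - exp(-k * 0.5)) * exp(-k * (tt - 0.5)))
  expect_equal(simi$conc_mg_L, analytic, tolerance = 1e-7)
  expect_equal(simi$times_h[which.max(simi$conc_mg_L)], 0.5)
  expect_identical(simi$times_h, tt)  # output grid honoured exactly
  expect_lt(mass_balance_error(simi), 1e-3)
  # NCA recovers dose/CL within 0.5%
  auc <- nca_auc(simi$times_h, simi$conc_mg_L, "inf", n_tail = 4)
  expect_equal(4 * s$weight_kg / auc, CL, tolerance = 5e-3)
})

test_that("superposition holds for linear kinetics", {
  theo <- builtin_drug("theophylline")
  s <- mean_subject(8, "male")
  tt <- seq(0, 48, 0.5)
  one <- simulate_minimal(theo, s, dose_regimen("iv_bolus", 4), tt)
  half <- simulate_minimal(theo, s, dose_regimen("iv_bolus", 2), tt)
  expect_equal(one$conc_mg_L, 2 * half$conc_mg_L, tolerance = 1e-6)
  # multiple dosing equals shifted single doses
  multi <- simulate_minimal(theo, s,
                            dose_regimen("iv_bolus", 2, interval_h = 12,
                                         n_doses = 2), tt)
  shift <- approx(tt, half$conc_mg_L, xout = pmax(tt - 12, 0))$y
  shift[tt < 12] <- 0
  expect_equal(multi$conc_mg_L, half$conc_mg_L + shift, tolerance = 1e-6)
  # full model linearity
  cef <- builtin_drug("ceftazidime")
  kp <- calibrate_kp_to_vss(predict_kp(cef), cef, adult)
  tc <- seq(0, 12, 0.25)
  a <- simulate_full(cef, adult, dose_regimen("iv_bolus", 50), tc, kp = kp)
  b <- simulate_full(cef, adult, dose_regimen("iv_bolus", 25), tc, kp = kp)
  expect_equal(a$conc_mg_L, 2 * b$conc_mg_L, tolerance = 1e-6)
})

test_that("with no clearance and unit tissue:blood partitioning the full
           model conserves and equilibrates the dose", {
  d <- inert_full_drug(bp = 0.8)
  kp <- unit_kb_kpset(bp = 0.8)
  sim <- simulate_full(d, adult, dose_regimen("iv_bolus", 1),
                       c(0, 1, 10, 100, 500), kp = kp)
  expect_lt(mass_balance_error(sim), 1e-3)
  total_v <- sum(adult$organ_volumes_L)
  dose <- 1 * adult$weight_kg
  # equilibrium venous plasma concentration = dose / (V_total x BP)
  expect_equal(sim$conc_mg_L[length(sim$conc_mg_L)],
               dose / (total_v * 0.8), tolerance = 1e-3)
})

test_that("full-model NCA clearance and moment-analysis Vss are internally
           consistent", {
  cef <- builtin_drug("ceftazidime")
  kp <- calibrate_kp_to_vss(predict_kp(cef), cef, adult)
  tt <- sort(unique(c(seq(0, 4, 0.05), seq(4, 48, 0.25))))
  sim <- simulate_full(cef, adult, dose_regimen("iv_infusion", 50,
                                                infusion_min = 30), tt,
                       kp = kp)
  expect_lt(mass_balance_error(sim), 1e-3)
  auc <- nca_auc(sim$times_h, sim$conc_mg_L, "inf", n_tail = 4)
  expect_equal(50 * adult$weight_kg / auc, total_cl(cef, adult),
               tolerance = 0.02)

  # slow-clearance short infusion: Vss = CL x (AUMC/AUC - T/2) recovers
  # the blood + lambda-weighted tissue volume (infusion input avoids the
  # venous mixing spike a bolus puts under the sampling grid)
  d <- inert_full_drug(bp = 0.8)
  d$cl_renal_adult_L_h <- 2
  kpu <- unit_kb_kpset(bp = 0.8)
  tt2 <- sort(unique(c(seq(0, 2, 0.01), seq(2, 250, 0.25))))
  reg2 <- dose_regimen("iv_infusion", 1, infusion_min = 15)
  sim2 <- simulate_full(d, adult, reg2, tt2, kp = kpu)
  t <- sim2$times_h; c <- sim2$conc_mg_L
  auc2 <- nca_auc(t, c, "t_last")
  aumc <- sum(diff(t) * (head(t * c, -1) + tail(t * c, -1)) / 2)
  lz <- nca_lambda_z(t, c, 4)
  auc_inf <- auc2 + tail(c, 1) / lz
  aumc_inf <- aumc + tail(c, 1) * tail(t, 1) / lz + tail(c, 1) / lz^2
  cl_nca <- 1 * adult$weight_kg / auc_inf
  vss_mom <- cl_nca * (aumc_inf / auc_inf - (15 / 60) / 2)
  vss_cfg <- vss_of(kpu, adult) * adult$weight_kg
  expect_equal(vss_mom, vss_cfg, tolerance = 0.03)
})

test_that("results are invariant to tolerance halving", {
  cef <- builtin_drug("ceftazidime")
  kp <- calibrate_kp_to_vss(predict_kp(cef), cef, adult)
  tt <- seq(0, 12, 0.25)
  reg <- dose_regimen("iv_infusion", 50, infusion_min = 30)
  a <- simulate_full(cef, adult, reg, tt, kp = kp)
  b <- simulate_full(cef, adult, reg, tt, kp = kp,
                     control = solver_control(rtol = 5e-9, atol = 5e-11))
  expect_lt(max(abs(a$conc_mg_L - b$conc_mg_L) / max(a$conc_mg_L)), 5e-4)
})

test_that("uniformly doubling body size leaves per-kg dosing concentrations
           unchanged", {
  cef <- builtin_drug("ceftazidime")
  kp <- calibrate_kp_to_vss(predict_kp(cef), cef, adult)
  big <- adult
  big$weight_kg <- 2 * adult$weight_kg
  big$organ_volumes_L <- 2 * adult$organ_volumes_L
  big$blood_flows_L_h <- 2 * adult$blood_flows_L_h
  big$cardiac_output_L_h <- 2 * adult$cardiac_output_L_h
  big$gfr_mL_min <- 2 * adult$gfr_mL_min
  tt <- seq(0, 12, 0.25)
  reg <- dose_regimen("iv_infusion", 50, infusion_min = 30)
  a <- simulate_full(cef, adult, reg, tt, kp = kp)
  b <- simulate_full(cef, big, reg, tt, kp = kp)
  expect_equal(a$conc_mg_L, b$conc_mg_L, tolerance = 1e-6)
})

test_that("engines reject drugs with the wrong distribution model", {
  expect_error(simulate_minimal(builtin_drug("fentanyl"), adult,
                                dose_regimen("iv_bolus", 1), c(0, 1)),
               "minimal")
  expect_error(simulate_full(builtin_drug("theophylline"), adult,
                             dose_regimen("iv_bolus", 1), c(0, 1)),
               "full")
  expect_error(dose_regimen("iv_infusion", 4, infusion_min = 0), "infusion")
  expect_error(dose_regimen("iv_bolus", -4), "dose")
})
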