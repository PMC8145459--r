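# PBPK disposition engines: tissue partitioning, Vss calibration, and the
# minimal (lumped) and full perfusion-rate-limited ODE models with
# intravenous bolus/infusion input and multiple dosing.

#' Dose regimen
#'
#' @param route "iv_bolus" or "iv_infusion".
#' @param dose_mg_per_kg dose per administration, mg/kg.
#' @param infusion_min infusion duration in minutes (0 for bolus).
#' @param interval_h dosing interval in hours (used when `n_doses > 1`).
#' @param n_doses number of doses.
#' @export
dose_regimen <- function(route = c("iv_infusion", "iv_bolus"), dose_mg_per_kg,
                         infusion_min = 0, interval_h = 24, n_doses = 1) {
  route <- match.arg(route)
  if (route == "iv_bolus") infusion_min <- 0
  stopifnot(dose_mg_per_kg > 0, infusion_min >= 0, n_doses >= 1)
  if (n_doses > 1 && interval_h <= 0)
    stop("interval_h must be positive for multiple dosing", call. = FALSE)
  if (route == "iv_infusion" && infusion_min <= 0)
    stop("iv_infusion requires infusion_min > 0", call. = FALSE)
  structure(list(route = route, dose_mg_per_kg = dose_mg_per_kg,
                 infusion_min = infusion_min, interval_h = interval_h,
                 n_doses = as.integer(n_doses)),
            class = "dose_regimen")
}

#' Stiff-solver settings
#'
#' @param rtol relative tolerance.
#' @param atol absolute tolerance (mg).
#' @param hmax maximum internal step (h); `Inf` leaves it to the solver.
#' @export
solver_control <- function(rtol = 1e-8, atol = 1e-10, hmax = Inf) {
  stopifnot(rtol > 0, atol > 0, hmax > 0)
  list(rtol = rtol, atol = atol, hmax = hmax)
}

.ionisation <- function(compound_type, pka1, pka2, ph) {
  # 1 + ionised:neutral ratio at the given pH
  switch(compound_type,
    neutral = 1,
    base = 1 + 10^(pka1 - ph),
    `monoprotic acid` = 1 + 10^(ph - pka1),
    `diprotic acid` = 1 + 10^(ph - pka1) + 10^(2 * ph - pka1 - pka2),
    ampholyte = {
      # acid + base pair; take pka1 acidic, pka2 basic when both present
      if (is.null(pka2)) 1 + 10^(pka1 - ph)
      else 1 + 10^(ph - min(pka1, pka2)) + 10^(max(pka1, pka2) - ph)
    })
}

.is_strong_base <- function(drug) {
  basic_pka <- switch(drug$compound_type,
    base = drug$pka1,
    ampholyte = if (!is.null(drug$pka2)) max(drug$pka1, drug$pka2) else drug$pka1,
    NULL)
  !is.null(basic_pka) && basic_pka >= 7
}

#' Predict tissue:plasma partition coefficients
#'
#' Mechanistic tissue composition based partitioning in the
#' Rodgers-Rowland style.  Moderate-to-strong bases (basic pKa >= 7,
#' including basic ampholytes) partition into tissue water, neutral lipid /
#' phospholipid, and acidic phospholipid, with the acidic-phospholipid
#' association constant back-calculated from the blood-to-plasma ratio.
#' Acids, neutrals and weak bases use tissue water, neutral lipid and an
#' albumin-type binding term back-calculated from the plasma fraction
#' unbound.  Every set is subsequently scaled by a single factor to match
#' the compound's reported Vss (see [calibrate_kp_to_vss()]), which makes
#' the composition details second-order.
#'
#' @param drug a `drug_model` with full physicochemistry.
#' @param system a [default_system()] object.
#' @return object of class `kp_set`: tissue:plasma coefficients for the 13
#'   modelled tissues and a scalar multiplier (initially 1).
#' @export
predict_kp <- function(drug, system = default_system()) {
  if (drug$compound_type != "neutral" && is.null(drug$pka1))
    stop("ionisable compound needs pka1 for Kp prediction", call. = FALSE)
  P <- 10^drug$log_p
  tc <- .tissue_composition
  fu <- drug$fu_plasma
  x_p <- .ionisation(drug$compound_type, drug$pka1, drug$pka2, .ph["plasma"])
  x_iw <- .ionisation(drug$compound_type, drug$pka1, drug$pka2, .ph["iw"])
  lipid <- function(f_nl, f_np) (P * f_nl + (0.3 * P + 0.7) * f_np) / x_p

  if (.is_strong_base(drug)) {
    pka_b <- if (drug$compound_type == "ampholyte")
      max(drug$pka1, drug$pka2) else drug$pka1
    hct <- system$adult_reference$hematocrit_frac
    kpu_bc <- (drug$bp_ratio - (1 - hct)) / (hct * fu)
    x_bc <- 1 + 10^(pka_b - .ph["bc"])
    bc_pred <- (x_bc / x_p) * .bc_comp["f_iw"] +
      lipid(.bc_comp["f_nl"], .bc_comp["f_np"])
    ka_ap <- max(0, (kpu_bc - bc_pred) * x_p /
                   (.bc_comp["ap"] * 10^(pka_b - .ph["bc"])))
    kpu <- tc$f_ew + (x_iw / x_p) * tc$f_iw +
      lipid(tc$f_nl, tc$f_np) +
      ka_ap * tc$ap * 10^(pka_b - .ph["iw"]) / x_p
  } else {
    # albumin-type binding back-calculated from fu
    ka_pr <- max(0, 1 / fu - 1 - lipid(.plasma_comp["f_nl"], .plasma_comp["f_np"]))
    kpu <- tc$f_ew + (x_iw / x_p) * tc$f_iw +
      lipid(tc$f_nl, tc$f_np) +
      ka_pr * tc$pr_ratio
  }
  kp <- unname(kpu) * fu
  names(kp) <- tc$tissue
  if (any(kp <= 0)) stop("non-positive Kp predicted", call. = FALSE)
  structure(list(kp = kp, scalar_lambda = 1, bp_ratio = drug$bp_ratio),
            class = "kp_set")
}

#' Plasma-referenced steady-state distribution volume of a Kp set
#'
#' `Vss = BP x V_blood + lambda x sum_t Kp_t V_t`, per kg of body weight.
#'
#' @param kpset a `kp_set`.
#' @param subject a `virtual_subject`.
#' @return Vss in L/kg.
#' @export
vss_of <- function(kpset, subject) {
  v <- subject$organ_volumes_L
  tis <- setdiff(names(v), "blood")
  (kpset$bp_ratio * v[["blood"]] +
     kpset$scalar_lambda * sum(kpset$kp[tis] * v[tis])) / subject$weight_kg
}

#' Calibrate a Kp set to a reported Vss
#'
#' Solves in closed form for the scalar multiplier such that the
#' plasma-referenced Vss of the adult reference subject equals the drug's
#' `vss_L_kg`.
#'
#' @param kpset a `kp_set` from [predict_kp()].
#' @param drug the `drug_model` providing the target Vss.
#' @param reference_subject the adult reference subject
#'   ([reference_adult()]).
#' @return the `kp_set` with `scalar_lambda` set.
#' @export
calibrate_kp_to_vss <- function(kpset, drug, reference_subject) {
  v <- reference_subject$organ_volumes_L
  tis <- setdiff(names(v), "blood")
  target <- drug$vss_L_kg * reference_subject$weight_kg
  blood_part <- kpset$bp_ratio * v[["blood"]]
  if (target <= blood_part)
    stop("target Vss (", drug$vss_L_kg, " L/kg) lies below the blood ",
         "contribution; infeasible", call. = FALSE)
  kpset$scalar_lambda <- (target - blood_part) / sum(kpset$kp[tis] * v[tis])
  kpset
}

#' Adult reference subject
#'
#' A 70 kg, 170 cm male with organ volumes from the population equations,
#' reference-table tissues at the oldest tabulated age, asymptotic cardiac
#' output and mature enzyme/renal function.  Used to anchor Vss calibration
#' and adult clearance.
#'
#' @param system a [default_system()] object.
#' @export
reference_adult <- function(system = default_system()) {
  ref <- system$adult_reference
  age <- ref$age_y
  wt <- ref$weight_kg
  ht <- ref$height_cm
  bsa <- body_surface_area(wt, ht)
  co <- cardiac_output(age, bsa)
  vols <- numeric(0)
  for (org in .recalibrated_organs)
    vols[org] <- organ_volume(org, ref$sex, weight_kg = wt, height_cm = ht,
                              bsa_m2 = bsa)
  for (org in .default_tissues)
    vols[org] <- default_tissue_volume(org, 18, wt)
  vols["rest"] <- wt - sum(vols * tissue_density(names(vols)))
  vols <- vols[.all_tissues]
  ont <- vapply(system$ontogeny, function(p) ontogeny_fraction(p, age),
                numeric(1))
  structure(list(
    age_y = age, sex = ref$sex, height_cm = ht, weight_kg = wt, bsa_m2 = bsa,
    cardiac_output_L_h = co,
    organ_volumes_L = vols,
    blood_flows_L_h = blood_flows(co, 18),
    hematocrit_frac = ref$hematocrit_frac,
    albumin_g_L = 46,
    gfr_mL_min = gfr_for(age, bsa, system),
    mppgl_mg_g = mppgl_for(age, system),
    enzyme_abundance_pmol_mg = system$enzyme_abundance_adult * ont
  ), class = "virtual_subject")
}

# ---- segment integrator -----------------------------------------------------

# Linear system dA/dt = M A + u(t) with piecewise-constant u (infusions) and
# instantaneous state jumps (boluses).  Integrates segment by segment so
# dose boundaries are honoured exactly.
.integrate_linear <- function(M, y0, doses, times, control) {
  # doses: data.frame(t_start, t_end, rate_mg_h, bolus_mg) (per event)
  bounds <- sort(unique(c(0, doses$t_start, doses$t_end, max(times))))
  bounds <- bounds[bounds <= max(times) + 1e-12]
  out_t <- sort(unique(c(times, bounds)))
  res <- matrix(NA_real_, nrow = length(out_t), ncol = length(y0))
  y <- y0
  rhs <- function(t, y, p) list(p$M %*% y + p$u)
  jac <- function(t, y, p) p$M
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    # bolus events at the start of this segment
    b <- doses$bolus_mg[abs(doses$t_start - t0) < 1e-12]
    if (length(b)) y[1] <- y[1] + sum(b)
    # constant infusion rate on (t0, t1)
    rate <- sum(doses$rate_mg_h[doses$t_start <= t0 + 1e-12 &
                                doses$t_end >= t1 - 1e-12])
    u <- numeric(length(y)); u[1] <- rate
    seg_t <- out_t[out_t >= t0 - 1e-12 & out_t <= t1 + 1e-12]
    seg_t <- sort(unique(c(t0, seg_t, t1)))
    sol <- lsoda(y = y, times = seg_t, func = rhs, parms = list(M = M, u = u),
                 jacfunc = jac, jactype = "fullusr",
                 rtol = control$rtol, atol = control$atol,
                 hmax = if (is.finite(control$hmax)) control$hmax else NULL)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failed to converge (istate ",
           attr(sol, "istate")[1], ")", call. = FALSE)
    keep <- match(round(out_t[out_t >= t0 - 1e-12 & out_t <= t1 + 1e-12], 10),
                  round(sol[, 1], 10))
    res[which(out_t >= t0 - 1e-12 & out_t <= t1 + 1e-12), ] <-
      sol[keep, -1, drop = FALSE]
    y <- as.numeric(sol[nrow(sol), -1])
  }
  list(times = out_t, states = res)
}

.dose_events <- function(regimen, weight_kg) {
  dose_mg <- regimen$dose_mg_per_kg * weight_kg
  starts <- (seq_len(regimen$n_doses) - 1) * regimen$interval_h
  dur_h <- regimen$infusion_min / 60
  if (dur_h > 0)
    data.frame(t_start = starts, t_end = starts + dur_h,
               rate_mg_h = dose_mg / dur_h, bolus_mg = 0)
  else
    data.frame(t_start = starts, t_end = starts, rate_mg_h = 0,
               bolus_mg = dose_mg)
}

.administered_at <- function(doses, t) {
  vapply(t, function(tt) {
    inf <- doses[doses$rate_mg_h > 0, , drop = FALSE]
    a <- 0
    if (nrow(inf))
      a <- a + sum(inf$rate_mg_h * pmax(0, pmin(tt, inf$t_end) - inf$t_start))
    a + sum(doses$bolus_mg[doses$t_start <= tt + 1e-12])
  }, numeric(1))
}

.new_sim_result <- function(times, conc, body_mg, elim_mg, administered_mg,
                            subject, drug) {
  structure(list(times_h = times, conc_mg_L = conc, body_mg = body_mg,
                 cumulative_eliminated_mg = elim_mg,
                 dose_administered_mg = administered_mg,
                 subject_age_y = subject$age_y,
                 subject_weight_kg = subject$weight_kg,
                 drug = drug$name),
            class = "pbpk_sim")
}

#' Mass-balance error of a simulation
#'
#' Maximum relative deviation of (amount in body + eliminated) from the
#' administered dose over all output times with non-zero dose.
#'
#' @param sim a simulation result.
#' @export
mass_balance_error <- function(sim) {
  adm <- sim$dose_administered_mg
  ok <- adm > 0
  if (!any(ok)) return(0)
  max(abs(sim$body_mg[ok] + sim$cumulative_eliminated_mg[ok] - adm[ok]) / adm[ok])
}

#' Simulate the minimal (lumped) disposition model
#'
#' One-compartment disposition with volume `Vss x WT` and clearance
#' [total_cl()], zero-order infusion input, linear superposition over
#' multiple doses.  Used for theophylline.
#'
#' @param drug a `drug_model` with `distribution = "minimal"`.
#' @param subject a `virtual_subject`.
#' @param regimen a [dose_regimen()].
#' @param times output times (h).
#' @param system a [default_system()] object.
#' @param control a [solver_control()].
#' @return a `pbpk_sim`: plasma concentration (mg/L) over time with mass
#'   bookkeeping.
#' @export
simulate_minimal <- function(drug, subject, regimen, times,
                             system = default_system(),
                             control = solver_control()) {
  if (drug$distribution != "minimal")
    stop("simulate_minimal() needs a minimal-distribution drug", call. = FALSE)
  eff <- effective_params(drug, subject)
  V <- eff$vss_L_kg * subject$weight_kg
  CL <- total_cl(drug, subject, system)
  k <- CL / V
  M <- matrix(c(-k, 0, k, 0), nrow = 2, byrow = TRUE)
  doses <- .dose_events(regimen, subject$weight_kg)
  sol <- .integrate_linear(M, c(0, 0), doses, times, control)
  idx <- match(round(times, 10), round(sol$times, 10))
  conc <- sol$states[idx, 1] / V
  .new_sim_result(times, conc, sol$states[idx, 1], sol$states[idx, 2],
                  .administered_at(doses, times), subject, drug)
}

# full-model state ordering
.full_states <- c("ven", "lung", "art", "brain", "heart", "kidney", "liver",
                  "pancreas", "spleen", "adipose", "muscle", "skin", "bone",
                  "gut", "rest", "met", "ren")

# build the rate matrix for the full perfusion-limited model
.full_matrix <- function(drug, subject, kp, system) {
  eff <- effective_params(drug, subject)
  bp <- eff$bp_ratio
  fu_b <- eff$fu_plasma / bp
  v <- subject$organ_volumes_L
  q <- subject$blood_flows_L_h
  co <- q[["lung"]]
  v_ven <- 2 / 3 * v[["blood"]]
  v_art <- 1 / 3 * v[["blood"]]
  kb <- kp$kp * kp$scalar_lambda / bp  # tissue:blood
  tis <- setdiff(.full_states, c("ven", "lung", "art", "met", "ren"))
  n <- length(.full_states)
  M <- matrix(0, n, n, dimnames = list(.full_states, .full_states))
  i <- function(s) match(s, .full_states)
  # escape rate of tissue t into its venous outflow, per unit amount
  kout <- function(t) q[[t]] / (v[[t]] * kb[[t]])

  clint_u <- whole_liver_clint(eff, subject, system)
  cl_r <- renal_cl(eff, subject, system)

  # venous: collects non-splanchnic tissues and total liver outflow
  direct <- c("brain", "heart", "kidney", "adipose", "muscle", "skin",
              "bone", "rest")
  for (t in direct) M[i("ven"), i(t)] <- kout(t)
  M[i("ven"), i("liver")] <- q[["liver"]] / (v[["liver"]] * kb[["liver"]])
  M[i("ven"), i("ven")] <- -co / v_ven
  # lung in series between venous and arterial blood
  M[i("lung"), i("ven")] <- co / v_ven
  M[i("lung"), i("lung")] <- -co / (v[["lung"]] * kb[["lung"]])
  M[i("art"), i("lung")] <- co / (v[["lung"]] * kb[["lung"]])
  M[i("art"), i("art")] <- -co / v_art
  # renal clearance applied on venous plasma so that the plasma clearance
  # recovered from venous sampling equals the GFR-scaled CL_R exactly
  M[i("ven"), i("ven")] <- M[i("ven"), i("ven")] - cl_r / (bp * v_ven)
  M[i("ren"), i("ven")] <- cl_r / (bp * v_ven)
  # perfusion-limited tissues fed from arterial blood
  for (t in setdiff(tis, "liver")) {
    M[i(t), i("art")] <- q[[t]] / v_art
    M[i(t), i(t)] <- -kout(t)
  }
  # liver: hepatic artery + portal inflow; well-stirred elimination on
  # liver outflow blood
  q_ha <- q[["hepatic_artery"]]
  M[i("liver"), i("art")] <- q_ha / v_art
  # remove the arterial draw already added for portal organs? (they keep it;
  # their outflow is redirected to the liver instead of venous blood)
  for (t in c("gut", "spleen", "pancreas")) {
    M[i("liver"), i(t)] <- kout(t)
    M[i("ven"), i(t)] <- 0
  }
  k_liv_out <- q[["liver"]] / (v[["liver"]] * kb[["liver"]])
  k_met <- fu_b * clint_u / (v[["liver"]] * kb[["liver"]])
  M[i("liver"), i("liver")] <- -(k_liv_out + k_met)
  M[i("met"), i("liver")] <- k_met
  list(M = M, v_ven = v_ven, bp = bp)
}

#' Simulate the full perfusion-rate-limited model
#'
#' Venous and arterial blood, lung, and twelve perfusion-limited tissues.
#' The liver receives hepatic-arterial plus portal (gut, spleen, pancreas)
#' inflow and eliminates by unbound intrinsic clearance on its outflow
#' (well-stirred equivalence); the GFR-scaled renal clearance acts on
#' venous plasma, which makes the clearance recovered from venous-plasma
#' NCA equal the configured plasma clearance.  Dosing enters venous blood.
#'
#' @param drug a `drug_model` with `distribution = "full_perfusion_limited"`.
#' @param subject a `virtual_subject`.
#' @param regimen a [dose_regimen()].
#' @param times output times (h).
#' @param kp a calibrated `kp_set`; computed (and calibrated to the adult
#'   reference) when omitted.
#' @param system a [default_system()] object.
#' @param control a [solver_control()].
#' @return a `pbpk_sim` with venous plasma concentration in mg/L.
#' @export
simulate_full <- function(drug, subject, regimen, times, kp = NULL,
                          system = default_system(),
                          control = solver_control()) {
  if (drug$distribution != "full_perfusion_limited")
    stop("simulate_full() needs a full-model drug", call. = FALSE)
  if (is.null(kp))
    kp <- calibrate_kp_to_vss(predict_kp(drug, system), drug,
                              reference_adult(system))
  mats <- .full_matrix(drug, subject, kp, system)
  doses <- .dose_events(regimen, subject$weight_kg)
  y0 <- numeric(length(.full_states))
  sol <- tryCatch(
    .integrate_linear(mats$M, y0, doses, times, control),
    error = function(e)
      stop("solver failure for subject (age ",
           signif(subject$age_y, 3), " y, ", signif(subject$weight_kg, 3),
           " kg, drug ", drug$name, "): ", conditionMessage(e), call. = FALSE))
  idx <- match(round(times, 10), round(sol$times, 10))
  st <- sol$states[idx, , drop = FALSE]
  n_body <- length(.full_states) - 2
  conc <- st[, 1] / mats$v_ven / mats$bp
  body <- rowSums(st[, seq_len(n_body), drop = FALSE])
  elim <- st[, n_body + 1] + st[, n_body + 2]
  .new_sim_result(times, conc, body, elim, .administered_at(doses, times),
                  subject, drug)
}

#' Simulate one subject with the drug's configured distribution model
#'
#' @inheritParams simulate_full
#' @export
simulate_subject <- function(drug, subject, regimen, times, kp = NULL,
                             system = default_system(),
                             control = solver_control()) {
  if (drug$distribution == "minimal")
    simulate_minimal(drug, subject, regimen, times, system, control)
  else
    simulate_full(drug, subject, regimen, times, kp, system, control)
}
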