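# Clinical trial simulation: replicate literature study designs on the
# virtual population, summarise NCA parameters, and evaluate predictions
# against observed values with the 2-fold criterion.

#' Trial design
#'
#' A literature study design: drug, age band, dosing, cohort structure and
#' sampling schedule.
#'
#' @param drug_name built-in drug name or a `drug_model`'s name.
#' @param age_min_y,age_max_y cohort age band (years).
#' @param regimen a [dose_regimen()].
#' @param n_per_trial subjects per replicate trial (>= 3, matching the
#'   literature inclusion criterion of more than three subjects).
#' @param n_trials number of replicate trials.
#' @param prop_female female fraction.
#' @param sampling_times_h sampling grid (h).
#' @param auc_horizon "inf" (single dose, AUC extrapolated to infinity) or
#'   "ss_24h" (AUC over the final 24 h of the simulated schedule, for
#'   multiple dosing to steady state).
#' @param seed RNG seed for the cohort draw.
#' @param conc_scale multiplier applied to reported concentrations/AUCs
#'   (1000 converts mg/L to ng/mL for microgram dosing).
#' @param name study label.
#' @export
trial_design <- function(drug_name, age_min_y, age_max_y, regimen,
                         n_per_trial = 10, n_trials = 10, prop_female = 0.5,
                         sampling_times_h, auc_horizon = c("inf", "ss_24h"),
                         seed = 1L, conc_scale = 1, name = drug_name) {
  auc_horizon <- match.arg(auc_horizon)
  if (n_per_trial < 3)
    stop("n_per_trial must be >= 3 (literature inclusion criterion)",
         call. = FALSE)
  stopifnot(inherits(regimen, "dose_regimen"), length(sampling_times_h) >= 2)
  structure(list(drug_name = drug_name, age_min_y = age_min_y,
                 age_max_y = age_max_y, regimen = regimen,
                 n_per_trial = as.integer(n_per_trial),
                 n_trials = as.integer(n_trials), prop_female = prop_female,
                 sampling_times_h = sort(unique(sampling_times_h)),
                 auc_horizon = auc_horizon, seed = seed,
                 conc_scale = conc_scale, name = name),
            class = "trial_design")
}

#' Read a trial design from YAML
#'
#' @param path YAML file with the [trial_design()] fields (the `regimen`
#'   block holds the [dose_regimen()] fields).
#' @export
read_trial_design <- function(path) {
  x <- read_yaml(path)
  reg <- do.call(dose_regimen, x$regimen)
  x$regimen <- NULL
  x$sampling_times_h <- unlist(x$sampling_times_h)
  do.call(trial_design, c(list(regimen = reg), x))
}

#' Packaged trial designs
#'
#' `list_builtin_trials()` names the shipped literature study designs;
#' `builtin_trial()` loads one.
#'
#' @export
list_builtin_trials <- function() {
  dir <- system.file("extdata", "trials", package = "pedpbpk", mustWork = TRUE)
  sub("\\.yaml$", "", sort(list.files(dir, pattern = "\\.yaml$")))
}

#' @param name a name from [list_builtin_trials()].
#' @rdname list_builtin_trials
#' @export
builtin_trial <- function(name) {
  path <- system.file("extdata", "trials", paste0(name, ".yaml"),
                      package = "pedpbpk")
  if (!nzchar(path))
    stop("unknown trial '", name, "'; see list_builtin_trials()",
         call. = FALSE)
  read_trial_design(path)
}

#' Run replicate trials of one study design
#'
#' Samples `n_trials` independent cohorts of `n_per_trial` subjects from
#' the virtual paediatric population restricted to the design's age band,
#' simulates each subject, runs NCA, and pools subjects across trials into
#' arithmetic mean/SD summaries of Cmax, clearance and AUC.
#'
#' @param design a [trial_design()].
#' @param drug a `drug_model`; the built-in matching `design$drug_name` by
#'   default.
#' @param system a [default_system()] object.
#' @param variability a [variability_config()].
#' @param keep_profiles keep per-subject concentration profiles
#'   (`$profiles`).
#' @return list with `summary` (parameter, mean, sd, n), `per_subject`
#'   (one NCA row per subject) and optionally `profiles`.
#' @export
run_trials <- function(design, drug = NULL, system = default_system(),
                       variability = variability_config(),
                       keep_profiles = FALSE) {
  stopifnot(inherits(design, "trial_design"))
  if (is.null(drug)) drug <- builtin_drug(design$drug_name)
  spec <- population_spec(design$age_min_y, design$age_max_y,
                          n_subjects = design$n_per_trial,
                          prop_female = design$prop_female,
                          variability = variability)
  kp <- if (drug$distribution == "full_perfusion_limited")
    calibrate_kp_to_vss(predict_kp(drug, system), drug,
                        reference_adult(system)) else NULL
  reg <- design$regimen
  daily_dose <- reg$dose_mg_per_kg * max(1, 24 / reg$interval_h *
                                           (reg$n_doses > 1))
  set.seed(design$seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1, design$n_trials)
  rows <- list()
  profiles <- list()
  for (tr in seq_len(design$n_trials)) {
    set.seed(trial_seeds[tr])
    for (k in seq_len(design$n_per_trial)) {
      s <- sample_subject(spec, system = system)
      sim <- simulate_subject(drug, s, reg, design$sampling_times_h,
                              kp = kp, system = system)
      t <- sim$times_h; conc <- sim$conc_mg_L
      if (design$auc_horizon == "ss_24h") {
        win <- t >= max(t) - 24 - 1e-9
        auc <- nca_auc(t[win] - min(t[win]), conc[win], "t_last")
        cl <- nca_cl_per_kg(daily_dose, auc)
        cmax <- nca_cmax(t[win], conc[win])
      } else {
        auc <- nca_auc(t, conc, "inf", n_tail = 4)
        cl <- nca_cl_per_kg(reg$dose_mg_per_kg, auc)
        cmax <- nca_cmax(t, conc)
      }
      rows[[length(rows) + 1]] <- data.frame(
        trial = tr, subject = k, age_y = s$age_y, sex = s$sex,
        weight_kg = s$weight_kg,
        cmax = cmax * design$conc_scale,
        auc = auc * design$conc_scale,
        cl_mL_h_kg = cl)
      if (keep_profiles)
        profiles[[length(profiles) + 1]] <- data.frame(
          trial = tr, subject = k, time_h = t, conc = conc * design$conc_scale)
    }
  }
  per_subject <- do.call(rbind, rows)
  summary <- data.frame(
    parameter = c("Cmax", "CL_mL_h_kg", "AUC"),
    mean = c(mean(per_subject$cmax), mean(per_subject$cl_mL_h_kg),
             mean(per_subject$auc)),
    sd = c(sd(per_subject$cmax), sd(per_subject$cl_mL_h_kg),
           sd(per_subject$auc)),
    n = nrow(per_subject))
  out <- list(design = design$name, summary = summary,
              per_subject = per_subject)
  if (keep_profiles) out$profiles <- do.call(rbind, profiles)
  out
}

#' Predicted-to-observed ratio
#'
#' @param predicted,observed the compared values; `observed` must be
#'   positive (NA observed propagates to an NA ratio).
#' @export
po_ratio <- function(predicted, observed) {
  ifelse(is.na(observed), NA_real_, {
    if (any(observed <= 0, na.rm = TRUE))
      stop("observed value must be positive", call. = FALSE)
    predicted / observed
  })
}

#' 2-fold acceptance test
#'
#' TRUE when the predicted-to-observed ratio lies in the inclusive band
#' \[0.5, 2.0\], the conventional acceptance criterion for population PBPK
#' verification.
#'
#' @param ratio a [po_ratio()] value (NA gives NA).
#' @export
within_twofold <- function(ratio) {
  ifelse(is.na(ratio), NA, ratio >= 0.5 & ratio <= 2.0)
}
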