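# Headline report tables: probe-drug PK verification against packaged
# observed values, and demographic verification against the national
# anthropometry survey bands.

#' Packaged observed PK reference values
#'
#' One row per study and PK parameter: the literature observed mean and
#' dispersion, together with the predictions reported by the reference
#' implementation of this population model (used for regression
#' comparison).
#'
#' @export
pk_reference_values <- function() {
  read.csv(system.file("extdata", "reference", "pk_reference.csv",
                       package = "pedpbpk", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Packaged anthropometry reference bands
#'
#' Observed mean, SD and 2.5th-97.5th percentile bands per age band, sex
#' and parameter from the national physique and health survey.
#'
#' @export
anthropometry_reference <- function() {
  read.csv(system.file("extdata", "reference", "anthropometry_bands.csv",
                       package = "pedpbpk", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Reproduce the probe-drug verification table
#'
#' Runs every packaged trial design against the virtual population, pools
#' the NCA parameters, joins the packaged observed values, and reports the
#' predicted-to-observed ratio with its 2-fold classification.  Ratios are
#' only populated where an observed value exists.
#'
#' @param seed master seed; per-study seeds are spawned deterministically
#'   from it so adding studies never perturbs existing ones.
#' @param system a [default_system()] object.
#' @param variability a [variability_config()].
#' @param trials trial names (defaults to every packaged design).
#' @return data frame: study, drug, parameter, units, predicted mean/SD,
#'   observed mean/SD, reference-implementation prediction, ratio,
#'   within_twofold.
#' @export
pk_verification_report <- function(seed = 20210511,
                                   system = default_system(),
                                   variability = variability_config(),
                                   trials = list_builtin_trials()) {
  ref <- pk_reference_values()
  set.seed(seed)
  study_seeds <- sample.int(.Machine$integer.max - 1, length(trials))
  out <- list()
  for (j in seq_along(trials)) {
    des <- builtin_trial(trials[j])
    des$seed <- study_seeds[j]
    res <- run_trials(des, system = system, variability = variability)
    sm <- res$summary
    rref <- ref[ref$study == des$name, , drop = FALSE]
    for (i in seq_len(nrow(rref))) {
      par <- rref$parameter[i]
      key <- switch(par, Cmax = "Cmax", CL = "CL_mL_h_kg", AUC = "AUC")
      pred <- sm$mean[sm$parameter == key]
      psd <- sm$sd[sm$parameter == key]
      obs <- rref$observed[i]
      ratio <- po_ratio(pred, obs)
      out[[length(out) + 1]] <- data.frame(
        study = des$name, drug = des$drug_name, parameter = par,
        units = rref$units[i],
        predicted = pred, predicted_sd = psd,
        observed = obs, observed_sd = rref$observed_sd[i],
        reference_predicted = rref$reference_predicted[i],
        reference_predicted_sd = rref$reference_predicted_sd[i],
        ratio = ratio, within_twofold = within_twofold(ratio))
    }
  }
  do.call(rbind, out)
}

# age bands used for demographic verification; the band below 11 years is
# compared against the survey's "<11" row over ages 9-11 (the row's mean
# height corresponds to about age 10)
.report_bands <- data.frame(
  band = c("lt11", "11-12", "13-14", "15-16", "17-18"),
  age_lo = c(9, 11, 13, 15, 17),
  age_hi = c(11, 12, 14, 16, 18),
  stringsAsFactors = FALSE)

#' Demographic verification report
#'
#' Simulates a virtual cohort with uniform ages, summarises height, weight,
#' haematocrit and albumin per sex and observed age band next to the
#' packaged survey values, and reports the coverage: the share of simulated
#' subjects falling inside the observed 2.5th-97.5th percentile band.
#'
#' @param n_subjects cohort size.
#' @param seed RNG seed.
#' @param prop_female female fraction.
#' @param variability a [variability_config()].
#' @param system a [default_system()] object.
#' @return data frame: band, sex, parameter, n_sim, sim_mean, sim_sd,
#'   obs_mean, obs_sd, coverage.
#' @export
demographics_report <- function(n_subjects = 4000, seed = 1L,
                                prop_female = 0.5,
                                variability = variability_config(),
                                system = default_system()) {
  spec <- population_spec(0, 18, n_subjects, prop_female, seed = seed,
                          variability = variability)
  pop <- generate_population(spec, system)
  ref <- anthropometry_reference()
  sim_col <- c(height_cm = "height_cm", weight_kg = "weight_kg",
               hematocrit_pct = "hematocrit_frac", albumin_g_L = "albumin_g_L")
  out <- list()
  for (b in seq_len(nrow(.report_bands))) {
    bb <- .report_bands[b, ]
    for (sx in c("male", "female")) {
      sel <- pop$sex == sx & pop$age_y >= bb$age_lo & pop$age_y <= bb$age_hi
      for (par in names(sim_col)) {
        if (par %in% c("hematocrit_pct", "albumin_g_L") && bb$band == "lt11")
          next  # sampled as constants below 11 y; no meaningful comparison
        rr <- ref[ref$band == bb$band & ref$sex == sx & ref$parameter == par, ]
        if (!nrow(rr)) next
        x <- pop[[sim_col[[par]]]][sel]
        if (par == "hematocrit_pct") x <- x * 100
        out[[length(out) + 1]] <- data.frame(
          band = bb$band, sex = sx, parameter = par, n_sim = sum(sel),
          sim_mean = mean(x), sim_sd = sd(x),
          obs_mean = rr$mean, obs_sd = rr$sd,
          coverage = mean(x >= rr$p2_5 & x <= rr$p97_5))
      }
    }
  }
  do.call(rbind, out)
}
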