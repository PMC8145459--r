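# Virtual Chinese paediatric population: growth curves, body composition,
# perfusion, renal maturation and subject sampling.

.check_sex <- function(sex) {
  if (!all(sex %in% c("male", "female")))
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  sex
}

# sex-specific height polynomial coefficients, constant term first
.ht_coef <- list(
  male = c(52.91366922873476, 34.65861528448144, -13.55291585347404,
           3.430362938724804, -0.4768902367461678, 0.03620932170728922,
           -0.001402674299655576, 0.00002161283469646225),
  female = c(49.589645987915, 41.44107707509581, -20.44446259722061,
             6.513533858016925, -1.184629069972546, 0.1254101134395548,
             -0.007615458476879155, 0.0002451527760663450,
             -0.000003237786173327683)
)

#' Population-mean height for age
#'
#' Evaluates the sex-specific height-for-age polynomial of the Chinese
#' paediatric growth model (degree 7 for males, degree 8 for females) at
#' full coefficient precision.
#'
#' @param age_y age in decimal years, in \[0, 18\].
#' @param sex "male" or "female" (recycled against `age_y`).
#' @return height in cm.
#' @export
#' @examples
#' height_for_age(c(0, 6, 12), "male")
height_for_age <- function(age_y, sex) {
  .check_sex(sex)
  if (any(age_y < 0 | age_y > 18))
    stop("height model is defined for ages 0-18 years", call. = FALSE)
  n <- max(length(age_y), length(sex))
  age_y <- rep_len(age_y, n)
  sex <- rep_len(sex, n)
  vapply(seq_len(n), function(i) {
    cf <- .ht_coef[[sex[i]]]
    # Horner evaluation, highest order first
    x <- age_y[i]
    acc <- 0
    for (k in rev(seq_along(cf))) acc <- acc * x + cf[k]
    acc
  }, numeric(1))
}

#' Population-mean weight given age and height
#'
#' Sex-specific weight model: a saturating age term plus an exponential
#' height-age term, `4.665 (1 - e^{-1.661 a}) + e^{0.025 HT - 0.015 a}` for
#' males and `5.087 (1 - e^{-1.793 a}) + e^{0.023 HT + 0.012 a}` for
#' females.
#'
#' @param age_y age in years.
#' @param height_cm height in cm.
#' @param sex "male" or "female".
#' @return weight in kg.
#' @export
weight_for <- function(age_y, height_cm, sex) {
  .check_sex(sex)
  if (any(age_y < 0 | age_y > 18))
    stop("weight model is defined for ages 0-18 years", call. = FALSE)
  ifelse(sex == "male",
         4.665 * (1 - exp(-1.661 * age_y)) + exp(0.025 * height_cm - 0.015 * age_y),
         5.087 * (1 - exp(-1.793 * age_y)) + exp(0.023 * height_cm + 0.012 * age_y))
}

#' Body surface area
#'
#' Haycock formula below 15 kg, Du Bois at or above 15 kg.
#'
#' @param weight_kg weight in kg.
#' @param height_cm height in cm.
#' @return body surface area in m^2.
#' @export
body_surface_area <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be positive", call. = FALSE)
  ifelse(weight_kg < 15,
         weight_kg^0.5378 * height_cm^0.3964 * 0.024265,
         weight_kg^0.425 * height_cm^0.725 * 0.007246)
}

#' Cardiac output
#'
#' `CO = BSA x (197.444 + 126.667 (e^{-0.06 a} - e^{-0.774 a}))` L/h, the
#' same for both sexes.  Beyond age 18 the double exponential decays toward
#' the adult asymptote, so the formula is also used for the adult reference
#' subject.
#'
#' @param age_y age in years (>= 0).
#' @param bsa_m2 body surface area in m^2.
#' @return cardiac output in L/h.
#' @export
cardiac_output <- function(age_y, bsa_m2) {
  if (any(age_y < 0)) stop("age must be non-negative", call. = FALSE)
  if (any(bsa_m2 <= 0)) stop("BSA must be positive", call. = FALSE)
  bsa_m2 * (197.444 + 126.667 * (exp(-0.06 * age_y) - exp(-0.774 * age_y)))
}

#' Recalibrated organ volume
#'
#' Sex-specific volume equations for the six organs with population-specific
#' growth models (brain, heart, kidney, liver, pancreas, spleen).  Printed
#' denominators 1.04, 1.05 and 1.06 are tissue densities (g/mL) converting
#' organ mass to volume.
#'
#' @param organ one of brain, heart, kidney, liver, pancreas, spleen.
#' @param sex "male" or "female".
#' @param weight_kg,height_cm,bsa_m2 body size; only the arguments an
#'   organ's equation uses need be supplied.
#' @return volume in litres.
#' @export
organ_volume <- function(organ, sex, weight_kg = NULL, height_cm = NULL,
                         bsa_m2 = NULL) {
  .check_sex(sex)
  if (!organ %in% .recalibrated_organs)
    stop("no recalibrated equation for '", organ,
         "'; use default_tissue_volume() for reference-table tissues",
         call. = FALSE)
  male <- sex == "male"
  wt <- weight_kg; ht <- height_cm; bsa <- bsa_m2
  switch(organ,
    brain = if (male) 0.473 * wt - 0.08754 * wt * log(ht)
            else 0.483548 * wt - 0.090402 * wt * log(ht),
    heart = if (male) 0.13 * bsa^1.26 / 1.04 else 0.1277 * bsa^1.3055 / 1.04,
    kidney = if (male) 13.028 * wt^0.713 / 1000
             else (5.509 * wt^0.761 + 5.837 * wt^0.762) / 1000,
    liver = if (male) 0.679 * bsa^1.0345 else 0.695 * bsa^1.125,
    pancreas = if (male) exp(-3.5 + 1.997 * log(ht / 100)) / 1.05
               else exp(-3.549 + 2.251 * log(ht / 100)) / 1.05,
    spleen = if (male) 0.023 * (ht / 100) * wt^0.351 / 1.06
             else 0.017 * (ht / 100) * wt^0.41 / 1.06)
}

#' Reference-table tissue volume
#'
#' Tissues without population-specific equations (lung, adipose, muscle,
#' skin, bone, gut, blood) use an age-indexed fraction-of-body-weight
#' reference table, linearly interpolated in age.  The residual rest-of-body
#' tissue closes the mass balance and is computed during subject assembly,
#' not here.
#'
#' @param organ one of lung, adipose, muscle, skin, bone, gut, blood.
#' @param age_y age in years; ages beyond the table range use the nearest row.
#' @param weight_kg body weight in kg.
#' @return volume in litres (density 1.0 g/mL for these tissues).
#' @export
default_tissue_volume <- function(organ, age_y, weight_kg) {
  if (!organ %in% .default_tissues)
    stop("'", organ, "' is not a reference-table tissue", call. = FALSE)
  frac <- vapply(age_y, function(a) .interp_row(.tissue_mass_fraction, a)[organ],
                 numeric(1))
  unname(frac * weight_kg / 1.0)
}

#' Organ blood flows for a given cardiac output
#'
#' Splits cardiac output over the systemic organs using the age-indexed
#' perfusion-fraction table.  Liver flow is hepatic artery plus the portal
#' inflow (gut + spleen + pancreas); the residual "rest" flow closes the sum
#' so that total venous return equals cardiac output.
#'
#' @param cardiac_output_L_h cardiac output in L/h.
#' @param age_y age in years.
#' @return named vector of flows in L/h, including `liver` (total),
#'   `hepatic_artery`, the portal organs, and `lung` (= cardiac output).
#' @export
blood_flows <- function(cardiac_output_L_h, age_y) {
  fr <- .interp_row(.flow_fraction, age_y)
  if (any(fr < 0)) stop("perfusion fractions must be non-negative", call. = FALSE)
  total_named <- sum(fr)
  if (total_named >= 1)
    stop("perfusion fractions exceed 1 before closure", call. = FALSE)
  rest <- 1 - total_named
  f <- c(fr, rest = rest)
  q <- f * cardiac_output_L_h
  liver <- q[["ha"]] + q[["gut"]] + q[["spleen"]] + q[["pancreas"]]
  out <- c(brain = q[["brain"]], heart = q[["heart"]], kidney = q[["kidney"]],
           liver = liver, hepatic_artery = q[["ha"]], gut = q[["gut"]],
           spleen = q[["spleen"]], pancreas = q[["pancreas"]],
           adipose = q[["adipose"]], muscle = q[["muscle"]], skin = q[["skin"]],
           bone = q[["bone"]], rest = q[["rest"]],
           lung = cardiac_output_L_h)
  out
}

#' Flow to a single organ of a subject
#'
#' @param organ organ name as in [blood_flows()].
#' @param subject a `virtual_subject`.
#' @return flow in L/h.
#' @export
blood_flow <- function(organ, subject) {
  q <- subject$blood_flows_L_h
  if (!organ %in% names(q)) stop("unknown organ '", organ, "'", call. = FALSE)
  unname(q[[organ]])
}

#' Glomerular filtration rate with maturation
#'
#' `GFR = GFR_adult,1.73 x maturation(PMA) x BSA / 1.73` with a sigmoid Hill
#' maturation function of postmenstrual age (PMA, weeks); term birth is
#' PMA = 40 weeks.
#'
#' @param age_y postnatal age in years (term subjects).
#' @param bsa_m2 body surface area in m^2.
#' @param system a [default_system()] constants object (GFR parameters).
#' @return GFR in mL/min.
#' @export
gfr_for <- function(age_y, bsa_m2, system = default_system()) {
  g <- system$gfr
  pma <- g$term_pma_weeks + age_y * 52.1775
  mat <- pma^g$hill / (pma^g$hill + g$tm50_weeks^g$hill)
  g$adult_mL_min_1p73 * mat * bsa_m2 / 1.73
}

#' Haematocrit and serum albumin for age and sex
#'
#' For ages 11 and above, samples Normal(mean, SD) from the observed
#' age-band table, truncated to the observed 2.5th-97.5th percentile band.
#' Below 11 years the survey provides no granularity and constant defaults
#' (haematocrit 0.38, albumin 44 g/L) are used.
#'
#' @param age_y age in years.
#' @param sex "male" or "female".
#' @param sd_scale multiplier on the band SD; 0 returns the band mean.
#' @return named vector `c(hematocrit_frac, albumin_g_L)`.
#' @export
hematocrit_albumin_for <- function(age_y, sex, sd_scale = 1) {
  .check_sex(sex)
  if (age_y < 11) return(c(hematocrit_frac = 0.38, albumin_g_L = 44))
  b <- .hct_alb_bands
  row <- b[b$sex == sex & age_y >= b$age_lo & age_y < b$age_hi, ]
  if (nrow(row) != 1) stop("no haematocrit/albumin band for age ", age_y)
  draw_trunc <- function(mean, sd, lo, hi) {
    if (sd_scale == 0 || sd == 0) return(mean)
    for (i in 1:100) {
      x <- rnorm(1, mean, sd * sd_scale)
      if (x >= lo && x <= hi) return(x)
    }
    mean
  }
  c(hematocrit_frac = draw_trunc(row$hct_mean, row$hct_sd, row$hct_lo, row$hct_hi) / 100,
    albumin_g_L = draw_trunc(row$alb_mean, row$alb_sd, row$alb_lo, row$alb_hi))
}

#' Inter-individual variability settings
#'
#' Lognormal coefficients of variation applied during subject sampling, with
#' symmetric truncation at `truncation_sd` standard deviates (violations are
#' resampled).  Defaults are calibrated to the observed SD/mean ratios of
#' the national anthropometry survey.
#'
#' @param cv_height CV of height about the mean growth curve.
#' @param cv_weight_residual residual CV of weight about the
#'   weight-given-height curve.
#' @param cv_organ CV of individual organ volumes; bulk tissues
#'   (adipose, muscle, skin, bone, gut, blood) use half this CV so that the
#'   whole-body mass balance closes without frequent resampling.
#' @param truncation_sd truncation bound in standard deviates.
#' @export
variability_config <- function(cv_height = 0.06, cv_weight_residual = 0.18,
                               cv_organ = 0.20, truncation_sd = 2.5) {
  stopifnot(cv_height >= 0, cv_weight_residual >= 0, cv_organ >= 0,
            truncation_sd > 0)
  structure(list(cv_height = cv_height,
                 cv_weight_residual = cv_weight_residual,
                 cv_organ = cv_organ,
                 truncation_sd = truncation_sd),
            class = "variability_config")
}

#' Population specification
#'
#' @param age_min_y,age_max_y age band in years, within \[0, 18\].
#' @param n_subjects number of subjects.
#' @param prop_female probability that a subject is female (or the female
#'   fraction under `sex_assignment = "alternating"`).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param variability a [variability_config()].
#' @param sex_assignment "random" (Bernoulli) or "alternating"
#'   (deterministic interleaving, for reproducible small cohorts).
#' @export
population_spec <- function(age_min_y, age_max_y, n_subjects,
                            prop_female = 0.5, seed = NULL,
                            variability = variability_config(),
                            sex_assignment = c("random", "alternating")) {
  sex_assignment <- match.arg(sex_assignment)
  if (!(age_min_y >= 0 && age_min_y <= age_max_y && age_max_y <= 18))
    stop("need 0 <= age_min_y <= age_max_y <= 18", call. = FALSE)
  if (prop_female < 0 || prop_female > 1)
    stop("prop_female must be in [0, 1]", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  structure(list(age_min_y = age_min_y, age_max_y = age_max_y,
                 n_subjects = as.integer(n_subjects),
                 prop_female = prop_female, seed = seed,
                 variability = variability, sex_assignment = sex_assignment),
            class = "population_spec")
}

#' Read a population specification from YAML or JSON
#'
#' Expected keys: `age_min`, `age_max`, `n`, `prop_female`, `seed` and an
#' optional `variability` block with the [variability_config()] fields.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @export
read_population_spec <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) fromJSON(path)
       else read_yaml(path)
  v <- x$variability
  vc <- if (is.null(v)) variability_config() else
    do.call(variability_config, v[intersect(names(v), names(formals(variability_config)))])
  population_spec(age_min_y = x$age_min, age_max_y = x$age_max,
                  n_subjects = x$n,
                  prop_female = if (is.null(x$prop_female)) 0.5 else x$prop_female,
                  seed = x$seed, variability = vc)
}

# mean-preserving truncated lognormal multiplier: E[mult] = 1 when
# truncation is wide; draws use a truncated standard normal deviate
.ln_mult <- function(cv, trunc_sd) {
  if (cv == 0) return(1)
  sig <- sqrt(log(1 + cv^2))
  repeat {
    z <- rnorm(1)
    if (abs(z) <= trunc_sd) break
  }
  exp(sig * z - sig^2 / 2)
}

#' Sample one virtual subject
#'
#' Draws age uniformly within the spec's band (unless given), assigns sex,
#' samples height and weight about the deterministic growth curves, and
#' derives every downstream physiological quantity: BSA, cardiac output,
#' the six recalibrated organ volumes and the reference-table tissues (each
#' with organ-level lognormal variability), perfusion, GFR, haematocrit,
#' albumin, microsomal protein and ontogeny-adjusted enzyme abundances.
#' The rest-of-body tissue closes the mass balance; organ draws leaving
#' less than 2% of body weight for it are resampled.
#'
#' @param spec a [population_spec()] (its `seed` is ignored here; seed the
#'   RNG with `set.seed()` or use [generate_population()]).
#' @param age,sex optional fixed age/sex overriding the random draw.
#' @param system a [default_system()] constants object.
#' @return a `virtual_subject` list.
#' @export
sample_subject <- function(spec, age = NULL, sex = NULL,
                           system = default_system()) {
  v <- spec$variability
  if (is.null(age)) age <- runif(1, spec$age_min_y, spec$age_max_y)
  if (is.null(sex)) sex <- if (runif(1) < spec$prop_female) "female" else "male"

  ht <- height_for_age(age, sex) * .ln_mult(v$cv_height, v$truncation_sd)
  wt <- weight_for(age, ht, sex) * .ln_mult(v$cv_weight_residual, v$truncation_sd)
  .assemble_subject(age, sex, ht, wt, v, system)
}

# build the full subject from age/sex/height/weight; organ-level noise from v
.assemble_subject <- function(age, sex, ht, wt, v, system) {
  bsa <- body_surface_area(wt, ht)
  co <- cardiac_output(age, bsa)

  frac <- .interp_row(.tissue_mass_fraction, age)  # one age lookup per subject
  for (try in 1:100) {
    vols <- numeric(0)
    for (org in .recalibrated_organs)
      vols[org] <- organ_volume(org, sex, weight_kg = wt, height_cm = ht,
                                bsa_m2 = bsa) * .ln_mult(v$cv_organ, v$truncation_sd)
    vols["lung"] <- frac[["lung"]] * wt * .ln_mult(v$cv_organ, v$truncation_sd)
    for (org in setdiff(.default_tissues, "lung"))
      vols[org] <- frac[[org]] * wt * .ln_mult(v$cv_organ / 2, v$truncation_sd)
    mass <- sum(vols * tissue_density(names(vols)))
    rest_mass <- wt - mass
    if (rest_mass >= 0.02 * wt) break
    if (try == 100) rest_mass <- 0.02 * wt  # degenerate configuration guard
  }
  vols["rest"] <- rest_mass / 1.0
  vols <- vols[.all_tissues]

  flows <- blood_flows(co, age)
  gfr <- gfr_for(age, bsa, system)
  ha <- hematocrit_albumin_for(age, sex)
  ont <- vapply(system$ontogeny,
                function(p) ontogeny_fraction(p, age), numeric(1))
  abund <- system$enzyme_abundance_adult[names(ont)] * ont

  structure(list(
    age_y = age, sex = sex, height_cm = ht, weight_kg = wt, bsa_m2 = bsa,
    cardiac_output_L_h = co,
    organ_volumes_L = vols,
    blood_flows_L_h = flows,
    hematocrit_frac = unname(ha["hematocrit_frac"]),
    albumin_g_L = unname(ha["albumin_g_L"]),
    gfr_mL_min = gfr,
    mppgl_mg_g = mppgl_for(age, system),
    enzyme_abundance_pmol_mg = abund
  ), class = "virtual_subject")
}

#' Deterministic mean subject
#'
#' The subject lying exactly on the population-mean curves (all CVs zero).
#'
#' @inheritParams sample_subject
#' @param age_y,sex fixed age and sex.
#' @export
mean_subject <- function(age_y, sex, system = default_system()) {
  v <- variability_config(0, 0, 0, truncation_sd = 2.5)
  ht <- height_for_age(age_y, sex)
  wt <- weight_for(age_y, ht, sex)
  .assemble_subject(age_y, sex, ht, wt, v, system)
}

#' Generate a virtual population
#'
#' @param spec a [population_spec()]; its `seed` (if non-NULL) seeds the RNG
#'   so repeated calls are bit-identical.
#' @param system a [default_system()] constants object.
#' @return data frame, one row per subject, organ maps flattened to
#'   `organ_<name>_L` / `flow_<name>_L_h` / `enz_<name>_pmol_mg` columns;
#'   also of class `virtual_population` carrying the subject list as an
#'   attribute.
#' @export
generate_population <- function(spec, system = default_system()) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_subjects
  sexes <- if (spec$sex_assignment == "alternating") {
    # deterministic even interleave honouring prop_female
    i <- seq_len(n)
    ifelse(floor(i * spec$prop_female) > floor((i - 1) * spec$prop_female),
           "female", "male")
  } else NULL
  subjects <- vector("list", n)
  for (i in seq_len(n))
    subjects[[i]] <- sample_subject(spec, sex = sexes[i], system = system)
  num <- do.call(rbind, lapply(subjects, .subject_numeric_row))
  df <- data.frame(id = seq_len(n),
                   age_y = num[, 1],
                   sex = vapply(subjects, `[[`, character(1), "sex"),
                   num[, -1, drop = FALSE],
                   stringsAsFactors = FALSE, check.names = FALSE)
  rownames(df) <- NULL
  structure(df, subjects = subjects,
            class = c("virtual_population", "data.frame"))
}

.subject_numeric_row <- function(s) {
  vols <- s$organ_volumes_L
  names(vols) <- paste0("organ_", names(vols), "_L")
  fl <- s$blood_flows_L_h
  names(fl) <- paste0("flow_", names(fl), "_L_h")
  en <- s$enzyme_abundance_pmol_mg
  names(en) <- paste0("enz_", names(en), "_pmol_mg")
  c(age_y = s$age_y, height_cm = s$height_cm, weight_kg = s$weight_kg,
    bsa_m2 = s$bsa_m2, cardiac_output_L_h = s$cardiac_output_L_h,
    hematocrit_frac = s$hematocrit_frac, albumin_g_L = s$albumin_g_L,
    gfr_mL_min = s$gfr_mL_min, mppgl_mg_g = s$mppgl_mg_g, vols, fl, en)
}

#' Subject list of a generated population
#' @param pop a `virtual_population`.
#' @export
population_subjects <- function(pop) attr(pop, "subjects")

#' Write a population to CSV
#' @param pop a `virtual_population` (or plain data frame).
#' @param path output file.
#' @export
write_population_csv <- function(pop, path) {
  write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(path)
}
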