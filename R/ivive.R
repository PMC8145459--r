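# In vitro - in vivo extrapolation: system constants, enzyme ontogeny,
# microsomal protein scaling, well-stirred hepatic clearance and
# GFR-scaled renal clearance.

#' Ontogeny profile for one enzyme
#'
#' Fractional activity relative to adult follows a Hill function of
#' postnatal age: `f(a) = f_birth + (1 - f_birth) a^n / (age50^n + a^n)`,
#' clamped to at most 1.
#'
#' @param enzyme enzyme name (e.g. "CYP3A4").
#' @param f_birth fraction of adult activity at birth, in \[0, 1\].
#' @param age50_y age at half-maximal maturation, years (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @export
ontogeny_profile <- function(enzyme, f_birth, age50_y, hill_n) {
  stopifnot(f_birth >= 0, f_birth <= 1, age50_y > 0, hill_n > 0)
  structure(list(enzyme = enzyme, f_birth = f_birth, age50_y = age50_y,
                 hill_n = hill_n), class = "ontogeny_profile")
}

#' Fraction of adult enzyme activity at a given age
#'
#' @param profile an [ontogeny_profile()].
#' @param age_y postnatal age in years (vectorised).
#' @return fraction in \[f_birth, 1\].
#' @export
ontogeny_fraction <- function(profile, age_y) {
  stopifnot(all(age_y >= 0))
  with(profile, pmin(1, f_birth + (1 - f_birth) *
                        age_y^hill_n / (age50_y^hill_n + age_y^hill_n)))
}

#' Microsomal protein per gram of liver
#'
#' Published log-polynomial age function,
#' `MPPGL = 10^(c0 + c1 a + c2 a^2 + c3 a^3)` mg/g, rising from about
#' 26 mg/g at birth toward about 40 mg/g in adults.
#'
#' @param age_y postnatal age in years (vectorised).
#' @param system a [default_system()] object carrying the coefficients.
#' @return mg microsomal protein per g liver.
#' @export
mppgl_for <- function(age_y, system = default_system()) {
  cf <- system$mppgl_coefs
  10^(cf[1] + cf[2] * age_y + cf[3] * age_y^2 + cf[4] * age_y^3)
}

#' System constants for the paediatric population
#'
#' Adult hepatic CYP abundances, in vivo ontogeny profiles, the MPPGL age
#' function, GFR maturation parameters and the adult reference anatomy.
#' These are system inputs of the simulator, configurable through
#' [read_system_file()]; the packaged defaults are the "CN-pediatric"
#' system file.
#'
#' @return object of class `pbpk_system`.
#' @export
default_system <- function() {
  if (!is.null(.pedpbpk_env$system)) return(.pedpbpk_env$system)
  sys <- structure(list(
    enzyme_abundance_adult = c(CYP1A2 = 52, CYP2D6 = 8, CYP2E1 = 61,
                               CYP3A4 = 137),
    ontogeny = list(
      CYP1A2 = ontogeny_profile("CYP1A2", 0.28, 0.60, 1.2),
      CYP2D6 = ontogeny_profile("CYP2D6", 0.10, 0.10, 1.0),
      CYP2E1 = ontogeny_profile("CYP2E1", 0.10, 0.50, 1.0),
      CYP3A4 = ontogeny_profile("CYP3A4", 0.25, 0.30, 1.0)
    ),
    mppgl_coefs = c(1.407, 0.0158, -0.000384, 3.3e-6),
    gfr = list(adult_mL_min_1p73 = 121, tm50_weeks = 47.7, hill = 3.4,
               term_pma_weeks = 40),
    liver_density_g_mL = 1.0,
    adult_reference = list(age_y = 30, sex = "male", weight_kg = 70,
                           height_cm = 170, hematocrit_frac = 0.45)
  ), class = "pbpk_system")
  stopifnot(all(sys$enzyme_abundance_adult > 0), sys$liver_density_g_mL > 0)
  .pedpbpk_env$system <- sys
  sys
}

#' Read system constants from YAML
#'
#' Loads a system-constants file (same layout as the packaged
#' `cn_pediatric_system.yaml`) and returns a `pbpk_system`, using the
#' packaged defaults for any block not present.
#'
#' @param path YAML file path.
#' @export
read_system_file <- function(path) {
  x <- read_yaml(path)
  sys <- default_system()
  if (!is.null(x$enzyme_abundance_adult))
    sys$enzyme_abundance_adult <- unlist(x$enzyme_abundance_adult)
  if (!is.null(x$ontogeny))
    sys$ontogeny <- lapply(setNames(names(x$ontogeny), names(x$ontogeny)),
                           function(e) do.call(ontogeny_profile,
                                               c(list(enzyme = e), x$ontogeny[[e]])))
  if (!is.null(x$mppgl_coefs)) sys$mppgl_coefs <- unlist(x$mppgl_coefs)
  if (!is.null(x$gfr)) sys$gfr <- utils::modifyList(sys$gfr, x$gfr)
  if (!is.null(x$adult_reference))
    sys$adult_reference <- utils::modifyList(sys$adult_reference, x$adult_reference)
  stopifnot(all(sys$enzyme_abundance_adult > 0))
  sys
}

#' Whole-liver unbound intrinsic clearance
#'
#' Scales per-pmol in vitro intrinsic clearances to the whole liver:
#' `sum_e CLint_e x abundance_e(age) x MPPGL(age) x liver mass`, converted
#' from uL/min to L/h, then multiplied by the drug's adult calibration
#' factor.  Subject abundances are already ontogeny-adjusted.
#'
#' @param drug a `drug_model`.
#' @param subject a `virtual_subject`.
#' @param system a [default_system()] object.
#' @return unbound intrinsic clearance in L/h (0 for drugs without enzyme
#'   kinetics).
#' @export
whole_liver_clint <- function(drug, subject, system = default_system()) {
  cl <- unlist(drug$clint_ul_min_pmol)
  if (!length(cl)) return(0)
  ab <- subject$enzyme_abundance_pmol_mg
  missing <- setdiff(names(cl), names(ab))
  if (length(missing))
    stop("no abundance configured for enzyme(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  liver_g <- subject$organ_volumes_L[["liver"]] * 1000 * system$liver_density_g_mL
  ul_min <- sum(cl * ab[names(cl)]) * subject$mppgl_mg_g * liver_g
  ul_min * 60 / 1e6 * drug$clint_calibration
}

#' Well-stirred hepatic clearance
#'
#' `CL_h = Q fu_b CLint_u / (Q + fu_b CLint_u)`, referenced to blood
#' concentration; always below liver blood flow.
#'
#' @param clint_u_L_h unbound intrinsic clearance, L/h.
#' @param q_liver_L_h total liver blood flow, L/h.
#' @param fu_blood fraction unbound in blood, `fu_plasma / bp_ratio`.
#' @return hepatic blood clearance, L/h.
#' @export
hepatic_cl_well_stirred <- function(clint_u_L_h, q_liver_L_h, fu_blood) {
  stopifnot(all(clint_u_L_h >= 0), all(q_liver_L_h > 0), all(fu_blood > 0))
  x <- fu_blood * clint_u_L_h
  q_liver_L_h * x / (q_liver_L_h + x)
}

#' GFR-scaled renal clearance
#'
#' `CL_R = CL_R,adult x GFR_subject / GFR_adult` where the adult reference
#' GFR is the system's 121 mL/min (1.73 m^2 subject).
#'
#' @param drug a `drug_model`.
#' @param subject a `virtual_subject`.
#' @param system a [default_system()] object.
#' @return renal plasma clearance, L/h.
#' @export
renal_cl <- function(drug, subject, system = default_system()) {
  drug$cl_renal_adult_L_h * subject$gfr_mL_min / system$gfr$adult_mL_min_1p73
}

#' Total systemic plasma clearance
#'
#' Hepatic well-stirred clearance (converted from blood to plasma reference
#' by the blood:plasma ratio) plus GFR-scaled renal clearance.  Drugs
#' without enzyme kinetics (ceftazidime, vancomycin) are therefore
#' renally-scaled only.
#'
#' @inheritParams renal_cl
#' @return total plasma clearance, L/h.
#' @export
total_cl <- function(drug, subject, system = default_system()) {
  eff <- effective_params(drug, subject)
  fu_b <- eff$fu_plasma / eff$bp_ratio
  clint <- whole_liver_clint(eff, subject, system)
  hep_b <- if (clint > 0)
    hepatic_cl_well_stirred(clint, blood_flow("liver", subject), fu_b) else 0
  hep_b * eff$bp_ratio + renal_cl(eff, subject, system)
}
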