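# Drug-model parameter sets: constructor/validator, packaged built-ins,
# JSON round-trip, and age-dependent effective parameters.

.compound_types <- c("ampholyte", "base", "diprotic acid", "monoprotic acid",
                     "neutral")
.builtin_names <- c("theophylline", "fentanyl", "ceftazidime", "vancomycin")

#' Construct and validate a drug model
#'
#' The parameter set of one compound: physicochemistry, blood binding,
#' distribution-model kind, elimination bookkeeping, per-enzyme in vitro
#' intrinsic clearance, adult renal clearance and steady-state volume of
#' distribution, with optional neonatal overrides.
#'
#' @param name compound name.
#' @param mw_g_mol molecular weight (g/mol).
#' @param log_p octanol-water log partition coefficient.
#' @param compound_type one of ampholyte, base, diprotic acid,
#'   monoprotic acid, neutral.
#' @param pka1,pka2 acid dissociation constants (optional for neutrals).
#' @param bp_ratio blood-to-plasma concentration ratio.
#' @param fu_plasma fraction unbound in plasma, in (0, 1\].
#' @param distribution "minimal" (lumped, parameterised by `vss_L_kg`) or
#'   "full_perfusion_limited".
#' @param elimination_fractions named list/vector with `metabolism` and/or
#'   `renal` fractions (bookkeeping metadata; the simulation uses the
#'   mechanistic clearances).
#' @param enzyme_fractions named fractions of metabolism per enzyme
#'   (metadata; must sum to <= 1).
#' @param clint_ul_min_pmol named per-enzyme unbound intrinsic clearance,
#'   uL/min/pmol P450.
#' @param cl_renal_adult_L_h adult renal clearance, L/h (plasma-referenced).
#' @param vss_L_kg steady-state volume of distribution, L/kg (plasma).
#' @param neonatal_overrides optional list with `fu_plasma` and/or
#'   `vss_L_kg` applied to neonates (age < 28 days).
#' @param clint_calibration scalar multiplier on the scaled unbound
#'   intrinsic clearance, used to anchor the adult reference clearance to an
#'   external in vivo value (default 1).
#' @return object of class `drug_model`.
#' @export
drug_model <- function(name, mw_g_mol, log_p, compound_type,
                       pka1 = NULL, pka2 = NULL, bp_ratio, fu_plasma,
                       distribution = c("minimal", "full_perfusion_limited"),
                       elimination_fractions = list(),
                       enzyme_fractions = list(),
                       clint_ul_min_pmol = list(),
                       cl_renal_adult_L_h = 0,
                       vss_L_kg = NULL,
                       neonatal_overrides = NULL,
                       clint_calibration = 1) {
  distribution <- match.arg(distribution)
  if (!compound_type %in% .compound_types)
    stop("compound_type must be one of: ",
         paste(.compound_types, collapse = ", "), call. = FALSE)
  ef <- unlist(elimination_fractions)
  if (length(ef) && (any(ef < 0) || any(ef > 1)))
    stop("elimination fractions must lie in [0, 1]", call. = FALSE)
  enf <- unlist(enzyme_fractions)
  if (length(enf) && sum(enf) > 1 + 1e-6)
    stop("enzyme fractions sum to ", round(sum(enf), 3),
         " (> 1); invalid model", call. = FALSE)
  if (!(fu_plasma > 0 && fu_plasma <= 1))
    stop("fu_plasma must lie in (0, 1]", call. = FALSE)
  if (bp_ratio <= 0) stop("bp_ratio must be positive", call. = FALSE)
  if (is.null(vss_L_kg))
    stop("vss_L_kg is required (minimal models use it directly; full models",
         " calibrate their partition coefficients to it)", call. = FALSE)
  if (vss_L_kg <= 0) stop("vss_L_kg must be positive", call. = FALSE)
  if (distribution == "full_perfusion_limited" &&
      compound_type != "neutral" && is.null(pka1))
    stop("ionisable compound with a full distribution model needs pka1",
         call. = FALSE)
  if (!is.null(neonatal_overrides)) {
    bad <- setdiff(names(neonatal_overrides), c("fu_plasma", "vss_L_kg"))
    if (length(bad))
      stop("unknown neonatal override field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(list(
    name = name, mw_g_mol = mw_g_mol, log_p = log_p,
    compound_type = compound_type, pka1 = pka1, pka2 = pka2,
    bp_ratio = bp_ratio, fu_plasma = fu_plasma, distribution = distribution,
    elimination_fractions = as.list(ef),
    enzyme_fractions = as.list(enf),
    clint_ul_min_pmol = as.list(unlist(clint_ul_min_pmol)),
    cl_renal_adult_L_h = cl_renal_adult_L_h,
    vss_L_kg = vss_L_kg,
    neonatal_overrides = neonatal_overrides,
    clint_calibration = clint_calibration
  ), class = "drug_model")
}

#' Packaged probe-drug models
#'
#' Returns one of the four shipped probe-drug parameter sets:
#' theophylline (CYP1A2 probe, minimal distribution model), fentanyl
#' (CYP3A4 probe, full model), ceftazidime and vancomycin (renally filtered,
#' full models).  The sets are read from the packaged JSON files and
#' validated on load.
#'
#' @param name one of `r paste(.builtin_names, collapse = ", ")`.
#' @export
builtin_drug <- function(name) {
  if (!name %in% .builtin_names)
    stop("unknown drug '", name, "'; built-ins are: ",
         paste(.builtin_names, collapse = ", "), call. = FALSE)
  key <- paste0("drug_", name)
  if (is.null(.pedpbpk_env[[key]])) {
    path <- system.file("extdata", "drugs", paste0(name, ".json"),
                        package = "pedpbpk", mustWork = TRUE)
    .pedpbpk_env[[key]] <- read_drug_model(path)
  }
  .pedpbpk_env[[key]]
}

#' Read / write drug-model JSON
#'
#' `read_drug_model()` loads and validates a JSON drug file (the same schema
#' as the packaged built-ins); `write_drug_model()` writes one such that
#' `read_drug_model(write_drug_model(m, path))` reproduces `m` field for
#' field.
#'
#' @param path JSON file path.
#' @export
read_drug_model <- function(path) {
  x <- fromJSON(path, simplifyVector = TRUE)
  required <- c("name", "mw_g_mol", "log_p", "compound_type", "bp_ratio",
                "fu_plasma", "distribution", "vss_L_kg")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("drug file ", path, " is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(drug_model, x[intersect(names(x), names(formals(drug_model)))])
}

#' @param model a `drug_model`.
#' @rdname read_drug_model
#' @export
write_drug_model <- function(model, path) {
  stopifnot(inherits(model, "drug_model"))
  x <- unclass(model)
  x <- x[!vapply(x, is.null, logical(1))]
  write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# neonatal window: first 28 days of life
.neonate_age_y <- 28 / 365.25

#' Age-effective drug parameters
#'
#' Applies the drug's neonatal overrides (fraction unbound, Vss) when the
#' subject is a neonate (age < 28 days); otherwise returns the base model.
#'
#' @param model a `drug_model`.
#' @param subject a `virtual_subject`, or a plain age in years.
#' @export
effective_params <- function(model, subject) {
  age <- if (inherits(subject, "virtual_subject")) subject$age_y else subject
  ov <- model$neonatal_overrides
  if (!is.null(ov) && age < .neonate_age_y) {
    if (!is.null(ov$fu_plasma)) model$fu_plasma <- ov$fu_plasma
    if (!is.null(ov$vss_L_kg)) model$vss_L_kg <- ov$vss_L_kg
  }
  model
}
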