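# Noncompartmental analysis: Cmax, trapezoidal AUC with log-linear
# terminal extrapolation, and dose-normalised clearance.

#' Maximum observed concentration
#'
#' @param times_h sampling times (h).
#' @param conc concentrations at those times.
#' @return Cmax in the concentration units supplied.
#' @export
nca_cmax <- function(times_h, conc) {
  if (length(conc) < 2) stop("need at least 2 samples", call. = FALSE)
  max(conc)
}

#' Terminal elimination rate constant
#'
#' Log-linear regression on the last `n_tail` positive-concentration
#' samples.
#'
#' @param times_h,conc the profile.
#' @param n_tail number of terminal points (>= 3).
#' @return lambda_z in 1/h, or `NA` when the terminal slope is
#'   non-negative.
#' @export
nca_lambda_z <- function(times_h, conc, n_tail = 3) {
  stopifnot(n_tail >= 3)
  ok <- conc > 0
  t <- times_h[ok]; c <- conc[ok]
  if (length(c) < n_tail) return(NA_real_)
  t <- tail(t, n_tail); c <- tail(c, n_tail)
  slope <- coef(lm(log(c) ~ t))[2]
  if (slope >= 0) return(NA_real_)
  unname(-slope)
}

#' Trapezoidal AUC
#'
#' Linear-up/log-down trapezoid over the sampled profile (the standard NCA
#' rule: linear trapezoid on rising or zero segments, log trapezoid on
#' declining positive segments).  `horizon = "inf"` adds the log-linear
#' extrapolation `C_last / lambda_z`; a non-estimable terminal slope falls
#' back to `t_last` with a warning.  `horizon = "24h"` integrates over the
#' first 24 hours (interpolating the 24 h point if needed).
#'
#' @param times_h,conc the profile (>= 2 samples).
#' @param horizon "t_last", "inf" or "24h".
#' @param n_tail terminal points for lambda_z.
#' @param method "lin_log" (default; linear up, log down) or "linear"
#'   (plain linear trapezoid on every segment).
#' @return AUC in conc x h units.
#' @export
nca_auc <- function(times_h, conc, horizon = c("t_last", "inf", "24h"),
                    n_tail = 3, method = c("lin_log", "linear")) {
  horizon <- match.arg(horizon)
  method <- match.arg(method)
  if (length(conc) < 2) stop("need at least 2 samples", call. = FALSE)
  o <- order(times_h)
  t <- times_h[o]; c <- conc[o]
  if (horizon == "24h") {
    if (max(t) < 24)
      stop("profile does not reach 24 h", call. = FALSE)
    c24 <- approx(t, c, xout = 24)$y
    keep <- t < 24
    t <- c(t[keep], 24); c <- c(c[keep], c24)
  }
  dt <- diff(t); c1 <- head(c, -1); c2 <- tail(c, -1)
  logdown <- if (method == "linear") rep(FALSE, length(dt))
             else c2 < c1 & c2 > 0 & c1 > 0
  seg <- ifelse(logdown,
                dt * (c1 - c2) / log(pmax(c1, 1e-300) / pmax(c2, 1e-300)),
                dt * (c1 + c2) / 2)
  auc <- sum(seg)
  if (horizon == "inf") {
    lz <- nca_lambda_z(t, c, n_tail)
    if (is.na(lz)) {
      warning("terminal slope not estimable; returning AUC to t_last")
    } else {
      auc <- auc + tail(c[c > 0], 1) / lz
    }
  }
  auc
}

#' Dose-normalised clearance
#'
#' `CL = dose / AUC x 1000` in mL/h/kg: for a single dose use the
#' administered dose per kg and AUC(0-inf); at steady state use the daily
#' dose per kg and AUC over 24 h.
#'
#' @param dose_mg_per_kg dose (single dose) or daily dose (steady state),
#'   mg/kg.
#' @param auc_mg_h_L the matching AUC, mg.h/L.
#' @return clearance in mL/h/kg.
#' @export
nca_cl_per_kg <- function(dose_mg_per_kg, auc_mg_h_L) {
  stopifnot(auc_mg_h_L > 0)
  dose_mg_per_kg / auc_mg_h_L * 1000
}
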