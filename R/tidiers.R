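# broom-style tidiers for the package's fitted objects.

#' @describeIn fit_recovery tidy coefficients of a FRAP recovery fit.
#' @param x a `frap_fit`.
#' @param ... unused.
#' @export
tidy.frap_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  vc <- stats::vcov(x$fit)
  se_A <- sqrt(max(vc["P", "P"] + vc["C", "C"] - 2 * vc["P", "C"], 0))
  tibble(term = c("A", "tau", "C"),
         estimate = c(x$A, x$tau, x$C),
         std.error = c(se_A, s["tau", "Std. Error"], s["C", "Std. Error"]))
}

#' @describeIn fit_recovery one-row fit summary (includes `t_half`).
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(t_half = x$t_half, tau = x$tau, A = x$A, C = x$C,
         residual_rms = x$residual_rms, n = nrow(x$data),
         flagged = length(x$flags) > 0)
}

#' @describeIn fit_saturation_curve tidy coefficients (`N_sat`, `K_V`) with
#'   standard errors from the fit covariance.
#' @param x a `saturation_fit`.
#' @param ... unused.
#' @export
tidy.saturation_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$covariance), 0))
  tibble(term = c("N_sat", "K_V"),
         estimate = c(x$N_sat, x$K_V),
         std.error = as.numeric(se))
}

#' @describeIn fit_saturation_curve one-row fit summary.
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble(N_sat = x$N_sat, K_V = x$K_V, residual_rms = x$residual_rms,
         n_bins = nrow(x$data), flagged = length(x$flags) > 0)
}

#' @describeIn fit_calibration tidy slope/intercept of the calibration line.
#' @param x a `blot_calibration`.
#' @param ... unused.
#' @export
tidy.blot_calibration <- function(x, ...) {
  generics::tidy(x$fit)
}

#' @describeIn fit_calibration one-row summary with `r_squared`.
#' @export
glance.blot_calibration <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared)
}
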