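#' Limiting-component CPAP-tubulin model parameters
#'
#' Constants of the mass-balance model linking cell volume, spindle volume and
#' cytoplasmic tubulin to the number of astral microtubules.  Falling free
#' tubulin liberates the centrosomal regulator CPAP from its inhibitory
#' tubulin complex; free CPAP raises centrosomal nucleation, and the astral
#' microtubule number follows a saturating Michaelis-Menten dependence on
#' cell volume, proportional to free CPAP.
#'
#' Units: 1 mg/ml is identically 1 fg/um^3, so the mass balance works in
#' (fg, um^3) without conversion constants.
#'
#' @param c_tot total tubulin concentration \[mg/ml\].  The default derives
#'   from the measured tubulin share of protein mass (1.5%) at the ESC mass
#'   density: 0.015 x 140 = 2.1 mg/ml.
#' @param rho_poly polymerized tubulin mass per spindle volume \[mg/ml\].
#' @param K_d half-inhibition concentration of the CPAP-tubulin interaction
#'   \[mg/ml\].  No measured value is available; package calibration value.
#' @param cpap_total total CPAP per cell \[counts, arbitrary\].
#' @param alpha astral microtubules per unit of free CPAP \[-\].
#' @param n_V total growing-microtubule (comet) number per cell volume
#'   \[1/um^3\]; experimentally constant across states.
#' @param lambda_bulk bulk microtubule number per spindle volume \[1/um^3\];
#'   calibrated so the morphometric astral estimator is unbiased against the
#'   generator's forward model at ESC defaults.
#' @param K_V half-saturation cell volume of the astral count \[um^3\]; the
#'   default 1,000 um^3 places the approach to plateau (75% of saturation)
#'   at the ~3,000 um^3 cell volume where the measured astral counts level
#'   off.
#'
#' @return an object of class `model_params`.
#' @export
#' @examples
#' model_params()
#' model_params(K_d = 0.5)$K_d
model_params <- function(c_tot = 2.1, rho_poly = 2, K_d = 0.3,
                         cpap_total = 440, alpha = 1, n_V = 0.05,
                         lambda_bulk = 0.330, K_V = 1000) {
  p <- list(c_tot = c_tot, rho_poly = rho_poly, K_d = K_d,
            cpap_total = cpap_total, alpha = alpha, n_V = n_V,
            lambda_bulk = lambda_bulk, K_V = K_V)
  for (f in names(p)) stop_if_not_positive(p[[f]], f)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  c_tot %g, rho_poly %g, K_d %g mg/ml; K_V %g um^3\n",
              x$c_tot, x$rho_poly, x$K_d, x$K_V))
  cat(sprintf("  cpap_total %g, alpha %g; n_V %g, lambda_bulk %g per um^3\n",
              x$cpap_total, x$alpha, x$n_V, x$lambda_bulk))
  invisible(x)
}

#' Free tubulin concentration from the cellular mass balance
#'
#' Total tubulin mass `c_tot * V_cell` minus the polymer mass locked in the
#' spindle (`rho_poly * V_spindle`), divided by the cell volume.  Mixing
#' volume is the whole cell.  Values that would be negative (mass-balance
#' violation) are clipped to zero and flagged.
#'
#' @param V_cell,V_spindle cell and spindle volumes \[um^3\]; vectorized.
#' @param params a [model_params()] object.
#' @param c_tot optional per-cell total tubulin concentration \[mg/ml\]
#'   overriding `params$c_tot` (e.g. tubulin fraction times each cell's own
#'   mass density); recycled against `V_cell`.
#' @return tibble with columns `c_free` \[mg/ml\] and `clipped` (logical).
#' @export
#' @examples
#' free_tubulin_concentration(2719, 0, model_params())$c_free # = c_tot
free_tubulin_concentration <- function(V_cell, V_spindle, params,
                                       c_tot = NULL) {
  stopifnot(inherits(params, "model_params"))
  c_tot <- c_tot %||% params$c_tot
  if (any(!is.finite(V_cell)) || any(V_cell <= 0)) {
    abort("`V_cell` must be positive.", class = "spindlescale_error_record")
  }
  if (any(V_spindle < 0) || any(V_spindle >= V_cell)) {
    abort("Records with V_spindle < 0 or V_spindle >= V_cell are inadmissible.",
          class = "spindlescale_error_record")
  }
  raw <- (c_tot * V_cell - params$rho_poly * V_spindle) / V_cell
  clipped <- raw < 0
  tibble(c_free = pmax(raw, 0), clipped = clipped)
}

#' Fraction of CPAP free of tubulin inhibition
#'
#' Single-site equilibrium with tubulin in excess:
#' `f = K_d / (K_d + c_free)`.  With no free tubulin all CPAP is liberated
#' (f = 1); at `c_free = K_d` half is.
#'
#' @param c_free free tubulin concentration \[mg/ml\], non-negative.
#' @param K_d half-inhibition concentration \[mg/ml\].
#' @return fraction in (0, 1]; vectorized.
#' @export
#' @examples
#' cpap_free_fraction(0, 0.3)    # 1
#' cpap_free_fraction(0.3, 0.3)  # 0.5
cpap_free_fraction <- function(c_free, K_d) {
  stop_if_not_positive(K_d, "K_d")
  if (any(!is.finite(c_free)) || any(c_free < 0)) {
    abort("`c_free` must be non-negative.", class = "spindlescale_error_params")
  }
  K_d / (K_d + c_free)
}

#' Predicted astral microtubule count
#'
#' The model's central statement: the astral microtubule number follows a
#' Michaelis-Menten dependence on cell volume and is proportional to free
#' CPAP,
#' \deqn{N(V) = N_{sat} \frac{V}{K_V + V},\qquad
#'       N_{sat} = \alpha\, \mathrm{CPAP}_{tot}\, f_{free}.}
#'
#' @param V_cell cell volume \[um^3\]; vectorized.
#' @param f_free free-CPAP fraction in (0, 1]; recycled.
#' @param fit either a `saturation_fit` (then `N_sat`, `K_V` come from the
#'   fit and `f_free` is ignored) or a [model_params()] object (mechanistic
#'   plateau `alpha * cpap_total * f_free`).
#' @return predicted counts, strictly increasing in `V_cell` and bounded by
#'   the plateau.
#' @export
#' @examples
#' p <- model_params()
#' predict_astral_count(p$K_V, f_free = 0.2, fit = p) # half the plateau
predict_astral_count <- function(V_cell, f_free = NULL, fit) {
  stop_if_not_positive(V_cell, "V_cell")
  if (inherits(fit, "saturation_fit")) {
    N_sat <- fit$N_sat
    K_V <- fit$K_V
  } else if (inherits(fit, "model_params")) {
    if (is.null(f_free)) {
      abort("`f_free` is required with mechanistic model params.",
            class = "spindlescale_error_params")
    }
    if (any(f_free <= 0) || any(f_free > 1)) {
      abort("`f_free` must lie in (0, 1].", class = "spindlescale_error_params")
    }
    N_sat <- fit$alpha * fit$cpap_total * f_free
    K_V <- fit$K_V
  } else {
    abort("`fit` must be a saturation_fit or model_params object.",
          class = "spindlescale_error_params")
  }
  N_sat * V_cell / (K_V + V_cell)
}

# Forward model used by the generator: per-cell expected astral count from
# morphometry and (optionally per-cell) total tubulin concentration.
astral_forward_model <- function(V_cell, V_spindle, params, c_tot = NULL,
                                 f_free_boost = 1) {
  ft <- free_tubulin_concentration(V_cell, V_spindle, params, c_tot = c_tot)
  f <- pmin(cpap_free_fraction(ft$c_free, params$K_d) * f_free_boost, 1)
  predict_astral_count(V_cell, f_free = f, fit = params)
}

#' Estimate astral microtubule counts from morphometry
#'
#' Book-keeping estimator resting on the experimentally constant number of
#' growing microtubules per cell volume: total microtubules `n_V * V_cell`
#' minus the spindle-bulk share `lambda_bulk * V_spindle`.  Negative raw
#' estimates are floored at zero and flagged (`clipped`); records violating
#' admissibility (`V_spindle >= V_cell`) are flagged `inadmissible` and
#' should be excluded from downstream fits.
#'
#' @param records tibble of per-cell records with columns `V_cell_um3` and
#'   `V_spindle_um3` (as produced by [generate_cell_population()] or
#'   [ingest_records()]).
#' @param params a [model_params()] object.
#' @return the input tibble with columns `astral_estimate_raw`,
#'   `astral_estimate` (floored), `clipped` and `inadmissible` appended.
#' @export
estimate_astral_counts <- function(records, params) {
  stopifnot(is.data.frame(records), inherits(params, "model_params"))
  need <- c("V_cell_um3", "V_spindle_um3")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")),
          class = "spindlescale_error_schema")
  }
  records <- as_tibble(records)
  raw <- params$n_V * records$V_cell_um3 -
    params$lambda_bulk * records$V_spindle_um3
  records$astral_estimate_raw <- raw
  records$astral_estimate <- pmax(raw, 0)
  records$clipped <- raw < 0
  records$inadmissible <- !(records$V_spindle_um3 >= 0 &
                              records$V_spindle_um3 < records$V_cell_um3)
  records
}

#' Fit the saturating astral-count curve
#'
#' Weighted nonlinear least squares of `N_sat * V / (K_V + V)` to binned mean
#' astral counts, with multistart over five jittered initializations
#' (`N_sat0 = 1.2 x max(count)`, `K_V0` = the bin center nearest half of
#' that) and the best residual kept.  `N_sat` is the predicted saturation
#' value of the astral microtubule number.
#'
#' @param bin_centers cell-volume bin centers \[um^3\].
#' @param mean_counts mean astral count per bin.
#' @param count_sds optional per-bin SDs for 1/sd^2 weighting; `NULL` for an
#'   unweighted fit.
#' @return an object of class `saturation_fit` with elements `N_sat`, `K_V`,
#'   `residual_rms`, `covariance` (2x2), `flags` (character) and `data`.
#'   `K_V` outside the sampled volume range by more than 10x is flagged
#'   `"K_V_non_identifiable"`.  Methods: [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' v <- seq(1250, 3750, by = 500)
#' y <- 60 * v / (1500 + v)
#' fit_saturation_curve(v, y)$N_sat
fit_saturation_curve <- function(bin_centers, mean_counts, count_sds = NULL) {
  stopifnot(length(bin_centers) == length(mean_counts))
  keep <- is.finite(bin_centers) & is.finite(mean_counts)
  if (!is.null(count_sds)) {
    stopifnot(length(count_sds) == length(mean_counts))
    keep <- keep & is.finite(count_sds) & count_sds > 0
  }
  v <- bin_centers[keep]; y <- mean_counts[keep]
  if (length(v) < 3) {
    abort("At least 3 bins are required to fit the saturation curve.",
          class = "spindlescale_error_fit")
  }
  w <- if (is.null(count_sds)) rep(1, length(v)) else 1 / count_sds[keep]^2
  # counts independent of volume: plateau-only data, K_V unidentifiable
  if (diff(range(y)) <= 1e-8 * max(abs(y), 1)) {
    return(structure(
      list(N_sat = mean(y), K_V = min(v) * 1e-6,
           residual_rms = sqrt(mean((y - mean(y))^2)),
           covariance = matrix(NA_real_, 2, 2,
                               dimnames = list(c("N_sat", "K_V"),
                                               c("N_sat", "K_V"))),
           flags = "K_V_non_identifiable",
           data = tibble(bin_center_um3 = v, mean_count = y,
                         count_sd = NA_real_),
           fit = NULL),
      class = "saturation_fit"))
  }
  n_sat0 <- 1.2 * max(y)
  k_v0 <- v[which.min(abs(y - n_sat0 / 2))]
  starts <- list(c(n_sat0, k_v0))
  jit <- with_seed_if(1L, replicate(4, stats::runif(2, 0.5, 2), simplify = FALSE))
  starts <- c(starts, lapply(jit, function(j) c(n_sat0 * j[1], k_v0 * j[2])))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ N_sat * v / (K_V + v),
        start = list(N_sat = s[1], K_V = s[2]),
        weights = w,
        lower = c(N_sat = 1e-9, K_V = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    abort("Saturation fit failed to converge from every start.",
          class = "spindlescale_error_fit")
  }
  cf <- coef(best$fit)
  flags <- character(0)
  if (cf[["K_V"]] > 10 * max(v) || cf[["K_V"]] < min(v) / 10) {
    flags <- c(flags, "K_V_non_identifiable")
  }
  covm <- tryCatch(stats::vcov(best$fit), error = function(e) {
    flags <<- c(flags, "covariance_unavailable")
    matrix(NA_real_, 2, 2, dimnames = list(c("N_sat", "K_V"), c("N_sat", "K_V")))
  })
  structure(
    list(N_sat = unname(cf[["N_sat"]]), K_V = unname(cf[["K_V"]]),
         residual_rms = sqrt(mean(stats::residuals(best$fit)^2)),
         covariance = covm, flags = flags,
         data = tibble(bin_center_um3 = v, mean_count = y,
                       count_sd = if (is.null(count_sds)) NA_real_ else count_sds[keep]),
         fit = best$fit),
    class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("<saturation_fit>  N(V) = N_sat * V / (K_V + V)\n")
  cat(sprintf("  N_sat (plateau) %.2f counts; K_V %.0f um^3; residual RMS %.3g\n",
              x$N_sat, x$K_V, x$residual_rms))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Per-state astral saturation analysis
#'
#' Bins per-cell astral counts by 500-um^3 cell-volume bins over the
#' observed volume range and fits the saturating curve for each state,
#' reproducing the model-versus-data comparison between the
#' undifferentiated and differentiating populations.
#'
#' Two numerical choices matter for unbiased plateau estimates and are
#' documented in the methods vignette: each bin enters at its mean cell
#' volume (bin centers systematically bias `K_V` low because cells are not
#' uniform within a bin), and bin means are weighted by their standard
#' errors (`sd/sqrt(n)`), not raw SDs, so sparsely populated edge bins do
#' not dominate.
#'
#' @param records per-cell tibble with `state`, `V_cell_um3` and a count
#'   column.
#' @param edges cell-volume bin edges \[um^3\].
#' @param count_col which count column to fit, default `"n_astral_true"`
#'   (the generator's forward-model draw); `"astral_estimate"` uses the
#'   morphometric estimator output of [estimate_astral_counts()].
#' @param min_n bins with fewer cells are dropped from the fit.
#' @param weighting `"sem"` (default) or `"none"`.
#' @return tibble with one row per state: `state`, `fit` (list column of
#'   `saturation_fit`), `N_sat`, `K_V`, `n_bins`.
#' @export
astral_saturation_analysis <- function(records, edges = seq(500, 5000, 500),
                                       count_col = "n_astral_true",
                                       min_n = 5,
                                       weighting = c("sem", "none")) {
  stopifnot(is.data.frame(records), count_col %in% names(records))
  weighting <- match.arg(weighting)
  binned <- bin_by_cell_volume(records, edges)
  per_state <- binned %>%
    filter(.data$bin != "unbinned") %>%
    group_by(.data$state, .data$bin, .data$bin_low, .data$bin_high) %>%
    summarise(n = dplyr::n(),
              mean_volume = mean(.data$V_cell_um3),
              mean_count = mean(.data[[count_col]]),
              sd_count = sd(.data[[count_col]]),
              sem_count = sd(.data[[count_col]]) / sqrt(dplyr::n()),
              .groups = "drop") %>%
    filter(.data$n >= min_n)
  per_state %>%
    group_by(.data$state) %>%
    dplyr::group_modify(function(d, key) {
      sat <- fit_saturation_curve(
        d$mean_volume, d$mean_count,
        if (weighting == "sem") d$sem_count else NULL)
      tibble(fit = list(sat), N_sat = sat$N_sat, K_V = sat$K_V,
             n_bins = nrow(d))
    }) %>%
    ungroup()
}
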