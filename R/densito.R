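check_ri_medium <- function(ri_medium) {
  if (any(ri_medium < 1.30) || any(ri_medium > 1.40)) {
    abort("`ri_medium` outside the plausible refractometer range 1.30-1.40.",
          class = "spindlescale_error_params")
  }
  invisible(ri_medium)
}

#' Convert raw refractive index to cellular mass density
#'
#' The tomography conversion
#' \deqn{\rho = \frac{(\mathrm{RI}_{raw}/10{,}000 - \mathrm{RI}_{medium})
#'   \times 1{,}000}{0.19}}
#' in mg/ml, with the protein refraction increment 0.19 ml/g and the
#' x10,000 integer raw-RI storage convention.  Negative densities (voxel
#' average below the medium) are flagged.
#'
#' @param ri_raw raw voxel-average RI values (x10,000 integer convention);
#'   vectorized.
#' @param ri_medium per-experiment medium refractive index (1.30-1.40).
#' @return tibble with `rho_mg_per_ml` and `flagged_negative`.
#' @export
#' @examples
#' mass_density_from_ri(13560, 1.337)$rho_mg_per_ml # 100
mass_density_from_ri <- function(ri_raw, ri_medium) {
  stop_if_not_positive(ri_raw, "ri_raw")
  check_ri_medium(ri_medium)
  rho <- ((ri_raw / 10000 - ri_medium) * 1000) / 0.19
  tibble(rho_mg_per_ml = rho, flagged_negative = rho < 0)
}

#' Average raw RI over a cell mask
#'
#' Arithmetic mean of the voxel values selected by the 3D cell mask; the
#' masked average is the quantity fed into [mass_density_from_ri()].
#'
#' @param voxel_values numeric vector of raw RI voxel values.
#' @param mask logical vector of the same length; must select >= 1 voxel.
#' @return the masked mean.
#' @export
#' @examples
#' average_masked_ri(c(13400, 13600, 99999), c(TRUE, TRUE, FALSE))
average_masked_ri <- function(voxel_values, mask) {
  if (length(voxel_values) != length(mask) || !is.logical(mask)) {
    abort("`mask` must be a logical vector matching `voxel_values`.",
          class = "spindlescale_error_params")
  }
  if (!any(mask)) {
    abort("Empty mask: no voxels to average.",
          class = "spindlescale_error_degenerate")
  }
  mean(voxel_values[mask])
}

#' Fit the tubulin-standard calibration curve
#'
#' Ordinary least squares of band signal against loaded tubulin mass over
#' the purified-tubulin standards.
#'
#' @param standards tibble with `loaded_tubulin_ng` and `band_signal`
#'   (>= 2 distinct masses).
#' @return object of class `blot_calibration`: `slope` \[signal/ng\],
#'   `intercept` \[signal\], `r_squared`, and the underlying `lm` fit.
#'   Methods: [tidy()], [glance()].
#' @export
#' @examples
#' s <- tibble::tibble(loaded_tubulin_ng = c(25, 50, 100),
#'                     band_signal = c(60, 110, 210))
#' fit_calibration(s)$slope # 2
fit_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("loaded_tubulin_ng", "band_signal") %in% names(standards)))
  if (length(unique(standards$loaded_tubulin_ng)) < 2) {
    abort("Calibration needs >= 2 distinct standard masses.",
          class = "spindlescale_error_degenerate")
  }
  fit <- lm(band_signal ~ loaded_tubulin_ng, data = standards)
  cf <- coef(fit)
  tss <- sum((standards$band_signal - mean(standards$band_signal))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(slope = unname(cf[["loaded_tubulin_ng"]]),
                 intercept = unname(cf[["(Intercept)"]]),
                 r_squared = r2, fit = fit),
            class = "blot_calibration")
}

#' @export
print.blot_calibration <- function(x, ...) {
  cat(sprintf("<blot_calibration> slope %.4g /ng, intercept %.4g, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Quantify the tubulin share of total protein mass
#'
#' Back-calculates tubulin mass per lysate lane through the standard
#' calibration curve, normalizes by the loaded total protein (with a
#' Coomassie load-correction factor: lane Coomassie signal over the
#' expectation for its nominal load, where the expectation is the pooled
#' signal-per-ug across lanes), and averages lanes:
#' `percent = 100 * tubulin_ng / (load_ug * 1000 * coomassie_correction)`.
#'
#' @param blot a `blot_dataset` (see [generate_blot_dataset()]) or a list
#'   with `standards` and `lanes` tibbles following the same schema.
#' @param coomassie_correction apply the Coomassie load correction
#'   (default TRUE; without Coomassie columns the factor is 1).
#' @return list with `lanes` (per-lane tibble: `loaded_total_protein_ug`,
#'   `tubulin_ng`, `coomassie_correction`, `percent`,
#'   `flagged_negative_mass`), `percent_mean`, `percent_sem` and
#'   `calibration`.
#' @export
quantify_tubulin_fraction <- function(blot, coomassie_correction = TRUE) {
  stopifnot(is.list(blot), !is.null(blot$standards), !is.null(blot$lanes))
  lanes <- as_tibble(blot$lanes)
  if (!nrow(lanes)) {
    abort("No lysate lanes to quantify.", class = "spindlescale_error_params")
  }
  cal <- fit_calibration(blot$standards)
  tub_ng <- (lanes$band_signal - cal$intercept) / cal$slope
  corr <- rep(1, nrow(lanes))
  if (coomassie_correction && "coomassie_total_signal" %in% names(lanes)) {
    per_ug <- sum(lanes$coomassie_total_signal) /
      sum(lanes$loaded_total_protein_ug)
    corr <- lanes$coomassie_total_signal /
      (per_ug * lanes$loaded_total_protein_ug)
  }
  pct <- 100 * tub_ng / (lanes$loaded_total_protein_ug * 1000 * corr)
  out <- tibble(loaded_total_protein_ug = lanes$loaded_total_protein_ug,
                tubulin_ng = tub_ng,
                coomassie_correction = corr,
                percent = pct,
                flagged_negative_mass = tub_ng < 0)
  list(lanes = out,
       percent_mean = mean(pct),
       percent_sem = if (nrow(out) > 1) sd(pct) / sqrt(nrow(out)) else NA_real_,
       calibration = cal)
}
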