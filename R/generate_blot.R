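#' Generate a synthetic quantitative-immunoblot dataset
#'
#' Emulates the tubulin quantification layout: defined masses of purified
#' tubulin blotted as calibration standards, lysate lanes at defined total
#' protein loads (tubulin band detected on the membrane), and a Coomassie
#' total-protein replica gel for load normalization.  Standard and lysate
#' band signals are linear in loaded tubulin mass with multiplicative
#' log-normal noise; the lysate tubulin mass is
#' `load_ug * 1000 * true_tubulin_percent / 100` ng.
#'
#' @param true_tubulin_percent ground-truth tubulin share of total protein
#'   mass, in percent (0, 100); the measured value is ~1.5.
#' @param standards_ng loaded tubulin masses of the calibration standards
#'   \[ng\], default 25/50/100; at least two distinct masses.
#' @param lane_loads_ug total protein loads of the lysate lanes \[ug\],
#'   default 4/2/1.
#' @param noise_cv coefficient of variation of the multiplicative signal
#'   noise (0 for exact lanes).
#' @param seed integer seed.
#' @param slope band signal per ng tubulin (arbitrary gain).
#' @param coomassie_gain Coomassie signal per ug total protein.
#' @return object of class `blot_dataset`: list of tibbles `standards`
#'   (`loaded_tubulin_ng`, `band_signal`) and `lanes` (`loaded_total_protein_ug`,
#'   `band_signal`, `coomassie_total_signal`), plus the ground truth in
#'   `true_tubulin_percent`.
#' @export
#' @examples
#' b <- generate_blot_dataset(1.5, noise_cv = 0, seed = 1)
#' quantify_tubulin_fraction(b)$percent_mean
generate_blot_dataset <- function(true_tubulin_percent = 1.5,
                                  standards_ng = c(25, 50, 100),
                                  lane_loads_ug = c(4, 2, 1),
                                  noise_cv = 0, seed = NULL,
                                  slope = 120, coomassie_gain = 5e4) {
  if (true_tubulin_percent <= 0 || true_tubulin_percent >= 100) {
    abort("`true_tubulin_percent` must lie in (0, 100).",
          class = "spindlescale_error_params")
  }
  if (length(unique(standards_ng)) < 2) {
    abort("At least two distinct standard masses are required.",
          class = "spindlescale_error_params")
  }
  if (noise_cv < 0) {
    abort("`noise_cv` must be non-negative.",
          class = "spindlescale_error_params")
  }
  stop_if_not_positive(standards_ng, "standards_ng")
  stop_if_not_positive(lane_loads_ug, "lane_loads_ug")
  with_seed_if(seed, {
    noise <- function(k) {
      if (noise_cv == 0) rep(1, k) else exp(rnorm(k, 0, noise_cv))
    }
    standards <- tibble(
      loaded_tubulin_ng = as.numeric(standards_ng),
      band_signal = slope * standards_ng * noise(length(standards_ng)))
    tub_ng <- lane_loads_ug * 1000 * true_tubulin_percent / 100
    lanes <- tibble(
      loaded_total_protein_ug = as.numeric(lane_loads_ug),
      band_signal = slope * tub_ng * noise(length(lane_loads_ug)),
      coomassie_total_signal = coomassie_gain * lane_loads_ug *
        noise(length(lane_loads_ug)))
    structure(list(standards = standards, lanes = lanes,
                   true_tubulin_percent = true_tubulin_percent),
              class = "blot_dataset")
  })
}

#' @export
print.blot_dataset <- function(x, ...) {
  cat("<blot_dataset>", nrow(x$standards), "standards,",
      nrow(x$lanes), "lysate lanes\n")
  invisible(x)
}
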