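#' Generate a synthetic population of mitotic cells
#'
#' Draws per-cell morphometric records with the statistical structure of the
#' published populations:
#' * cell volume from a normal truncated at `max(0, mean - 3 sd)`;
#' * spindle volume from a linear-through-origin scaling law with
#'   log-normal noise and a state-specific multiplicative subscaling factor,
#'   `V_spindle = spindle_fraction * (1 - subscaling_factor) * V_cell * exp(eps)`;
#' * summed centrosome volume proportional to cell volume, soft-capped where
#'   the state defines an upper limit (undifferentiated cells above
#'   ~3,000 um^3);
#' * mass density from the state's normal law;
#' * a ground-truth astral microtubule count drawn from the CPAP-tubulin
#'   forward model ([predict_astral_count()]) with Poisson noise, using each
#'   cell's own tubulin concentration (tubulin mass fraction x density).
#'
#' @param params a [state_params()] object.
#' @param n number of cells (>= 1).
#' @param seed integer seed; identical `(params, n, seed)` give identical
#'   output.  `NULL` uses the current RNG stream.
#' @param mparams a [model_params()] object for the astral forward model.
#' @return tibble with one row per cell: `cell_id`, `state`, `time_bin_h`,
#'   `V_cell_um3`, `V_spindle_um3`, `spindle_length_um`, `spindle_width_um`,
#'   `V_centrosome_um3`, `rho_mg_per_ml`, `mean_tubulin_signal`,
#'   `n_astral_true`.
#' @export
#' @examples
#' cells <- generate_cell_population(state_params("ESC"), n = 100, seed = 1)
#' mean(cells$V_cell_um3)
generate_cell_population <- function(params, n, seed = NULL,
                                     mparams = model_params()) {
  stopifnot(inherits(params, "state_params"), inherits(mparams, "model_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer.", class = "spindlescale_error_params")
  }
  with_seed_if(seed, {
    v_lo <- max(0, params$cell_volume_mean - 3 * params$cell_volume_sd)
    V <- rnorm_trunc(n, params$cell_volume_mean, params$cell_volume_sd,
                     lower = v_lo)
    eps <- rnorm(n, 0, params$scaling_noise_sd)
    Vs <- params$spindle_fraction * (1 - params$subscaling_factor) * V * exp(eps)
    # spindles are approximated as prolate ellipsoids with mild aspect noise
    aspect <- rnorm_trunc(n, 1.5, 0.1, lower = 1.05)
    width <- (6 * Vs / (pi * aspect))^(1 / 3)
    len <- aspect * width
    Vc <- softmin(params$centrosome_fraction * V,
                  if (is.na(params$centrosome_cap)) NULL else params$centrosome_cap,
                  params$centrosome_cap_scale)
    rho <- rnorm_trunc(n, params$mass_density_mean, params$mass_density_sd,
                       lower = 0)
    c_tot <- params$tubulin_mass_fraction * rho
    lambda_ast <- astral_forward_model(V, Vs, mparams, c_tot = c_tot,
                                       f_free_boost = params$f_free_boost)
    tibble(
      cell_id = sprintf("%s_%05d", params$state, seq_len(n)),
      state = params$state,
      time_bin_h = if (params$state == "DIF") {
        sample(c(24, 48, 72, 96, 120), n, replace = TRUE)
      } else rep(0, n),
      V_cell_um3 = V,
      V_spindle_um3 = Vs,
      spindle_length_um = len,
      spindle_width_um = width,
      V_centrosome_um3 = Vc,
      rho_mg_per_ml = rho,
      mean_tubulin_signal = c_tot * exp(rnorm(n, 0, 0.05)) / 2.1,
      n_astral_true = rpois(n, lambda_ast)
    )
  })
}

#' Synthesize raw refractive-index voxel averages from mass densities
#'
#' Inverse of the refractive-index-to-density conversion: a cell of dry-mass
#' density `rho` suspended in medium of refractive index `ri_medium` has an
#' average refractive index `ri_medium + 0.19 * rho / 1000` (protein
#' refraction increment 0.19 ml/g), stored in the x10,000 integer raw
#' convention of the tomography file schema.
#'
#' @param rho mass densities \[mg/ml\].
#' @param ri_medium medium refractive index (per-experiment refractometer
#'   value), default 1.337.
#' @return integer raw RI values (`round(10000 * ri)`).
#' @seealso [mass_density_from_ri()]
#' @export
#' @examples
#' ri_from_mass_density(140, 1.337)
ri_from_mass_density <- function(rho, ri_medium = 1.337) {
  if (any(rho < 0)) {
    abort("`rho` must be non-negative.", class = "spindlescale_error_params")
  }
  check_ri_medium(ri_medium)
  as.integer(round(10000 * (ri_medium + 0.19 * rho / 1000)))
}

#' Generate synthetic cell-division lineages
#'
#' Division times accumulate i.i.d. truncated-normal cell-cycle intervals
#' until the recording ends, emulating long-term tracking of individual cell
#' families.
#'
#' @param mean_cycle_s,sd_s cell-cycle length law \[s\].
#' @param total_duration_s recording duration \[s\] (>= one mean cycle).
#' @param n_families number of tracked families.
#' @param seed integer seed.
#' @return tibble with `family_id` and `division_time_s` (strictly
#'   increasing within each family).
#' @export
#' @examples
#' generate_lineages(36000, 0, 144000, n_families = 2, seed = 1)
generate_lineages <- function(mean_cycle_s, sd_s, total_duration_s,
                              n_families, seed = NULL) {
  stop_if_not_positive(mean_cycle_s, "mean_cycle_s")
  stop_if_not_positive(total_duration_s, "total_duration_s")
  if (sd_s < 0) abort("`sd_s` must be non-negative.",
                      class = "spindlescale_error_params")
  if (total_duration_s < mean_cycle_s) {
    abort("`total_duration_s` must cover at least one mean cycle.",
          class = "spindlescale_error_params")
  }
  stopifnot(n_families >= 1)
  with_seed_if(seed, {
    purrr::map_dfr(seq_len(n_families), function(f) {
      t <- 0; times <- numeric(0)
      repeat {
        dt <- rnorm_trunc(1, mean_cycle_s, sd_s, lower = 0)
        if (t + dt > total_duration_s) break
        t <- t + dt
        times <- c(times, t)
      }
      if (!length(times)) {
        return(tibble(family_id = sprintf("fam_%03d", f),
                      division_time_s = numeric(0)))
      }
      tibble(family_id = sprintf("fam_%03d", f), division_time_s = times)
    })
  })
}
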