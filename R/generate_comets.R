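#' Generate synthetic EB1 comet tracks
#'
#' Straight-line plus-end trajectories at a per-track growth speed drawn
#' from `Normal(comet_speed_mean, comet_speed_sd)` truncated positive,
#' sampled at the published 0.4-s frame interval.  Track durations are
#' uniform over a configurable range spanning the 2-4 s retention window of
#' the track filter plus shorter and longer rejects; start frames are
#' uniform over the video so that some tracks violate the start/end window
#' rule.  Each track carries a median-quality score and a generator-assigned
#' compartment label (`"astral"` or `"bulk"`) with state-specific odds.
#'
#' @param params a [state_params()] object.
#' @param n_cells number of cells.
#' @param tracks_per_cell tracks generated per cell (before filtering).
#' @param seed integer seed.
#' @param frame_interval_s seconds per frame (default 0.4).
#' @param duration_range_s uniform support of track durations \[s\];
#'   the default (1.2, 5.2) brackets the 2-4 s retention window.
#' @param video_frames number of frames in the video (frame indices
#'   `0:(video_frames - 1)`).
#' @param quality_mean_sd per-track mean quality law (normal); per-frame
#'   quality jitters around the track mean with SD 25.
#' @return tibble with one row per track point: `cell_id`, `track_id`,
#'   `frame`, `time_s`, `x_um`, `y_um`, `quality`, `compartment`,
#'   `V_cell_um3`, `speed_true_um_per_s`.
#' @export
#' @examples
#' tr <- generate_comet_tracks(state_params("ESC"), n_cells = 2,
#'                             tracks_per_cell = 5, seed = 1)
#' length(unique(tr$track_id))
generate_comet_tracks <- function(params, n_cells, tracks_per_cell, seed = NULL,
                                  frame_interval_s = 0.4,
                                  duration_range_s = c(1.2, 5.2),
                                  video_frames = 41,
                                  quality_mean_sd = c(400, 110)) {
  stopifnot(inherits(params, "state_params"), n_cells >= 1,
            tracks_per_cell >= 1)
  stop_if_not_positive(frame_interval_s, "frame_interval_s")
  stopifnot(length(duration_range_s) == 2,
            duration_range_s[1] > 0,
            duration_range_s[2] >= duration_range_s[1])
  with_seed_if(seed, {
    v_lo <- max(0, params$cell_volume_mean - 3 * params$cell_volume_sd)
    vols <- rnorm_trunc(n_cells, params$cell_volume_mean,
                        params$cell_volume_sd, lower = v_lo)
    purrr::map_dfr(seq_len(n_cells), function(ci) {
      purrr::map_dfr(seq_len(tracks_per_cell), function(ti) {
        speed <- rnorm_trunc(1, params$comet_speed_mean,
                             params$comet_speed_sd, lower = 0)
        dur <- runif(1, duration_range_s[1], duration_range_s[2])
        n_steps <- max(1L, as.integer(round(dur / frame_interval_s)))
        start_frame <- sample.int(max(1L, video_frames - n_steps), 1L) - 1L
        frames <- start_frame + 0:n_steps
        theta <- runif(1, 0, 2 * pi)
        origin <- runif(2, 0, 15)
        t_rel <- (0:n_steps) * frame_interval_s
        q_mean <- rnorm(1, quality_mean_sd[1], quality_mean_sd[2])
        tibble(
          cell_id = sprintf("%s_cell_%03d", params$state, ci),
          track_id = sprintf("%s_c%03d_t%04d", params$state, ci, ti),
          frame = frames,
          time_s = frames * frame_interval_s,
          x_um = origin[1] + speed * t_rel * cos(theta),
          y_um = origin[2] + speed * t_rel * sin(theta),
          quality = q_mean + rnorm(length(frames), 0, 25),
          compartment = sample(c("astral", "bulk"), 1,
                               prob = c(params$astral_prob,
                                        1 - params$astral_prob)),
          V_cell_um3 = vols[ci],
          speed_true_um_per_s = speed
        )
      })
    })
  })
}

# Closed-form power-law half-spindle profile: intensity (1 - x)^p has pole
# share 1 - 0.5^(p + 1); x^p has pole share 0.5^(p + 1).  Inverting gives an
# exact profile for any target pole fraction in (0, 1).
profile_from_pole_fraction <- function(target, grid) {
  stopifnot(target > 0, target < 1)
  if (target >= 0.5) {
    p <- log(1 - target) / log(0.5) - 1
    (1 - grid)^p
  } else {
    p <- log(target) / log(0.5) - 1
    grid^p
  }
}

#' Generate synthetic half-spindle intensity profiles
#'
#' Profiles run from the spindle pole (normalized distance 0) to the equator
#' (distance 1), both axes min-max normalized.  Each profile is built from a
#' power-law family whose integral share over distance \[0, 0.5\] equals a
#' per-profile target drawn from
#' `Normal(pole_fraction_mean, pole_fraction_sd)` (truncated to (0.05,
#' 0.95)), with optional small intensity noise.
#'
#' @param params a [state_params()] object (uses `pole_fraction_mean`,
#'   `pole_fraction_sd`).
#' @param n number of profiles.
#' @param seed integer seed.
#' @param n_points grid resolution (default 101, includes distance 0.5).
#' @param noise_sd additive intensity noise before re-normalization.
#' @return tibble with `profile_id`, `distance`, `intensity`,
#'   `pole_fraction_true`.
#' @export
#' @examples
#' pr <- generate_half_spindle_profiles(state_params("ESC"), n = 3, seed = 1)
#' range(pr$intensity)
generate_half_spindle_profiles <- function(params, n, seed = NULL,
                                           n_points = 101, noise_sd = 0) {
  stopifnot(inherits(params, "state_params"), n >= 1, n_points >= 11)
  if (params$pole_fraction_mean <= 0 || params$pole_fraction_mean >= 1) {
    abort("`pole_fraction_mean` must lie in (0, 1).",
          class = "spindlescale_error_params")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be non-negative.",
          class = "spindlescale_error_params")
  }
  grid <- seq(0, 1, length.out = n_points)
  with_seed_if(seed, {
    purrr::map_dfr(seq_len(n), function(k) {
      target <- if (params$pole_fraction_sd > 0) {
        min(max(rnorm(1, params$pole_fraction_mean, params$pole_fraction_sd),
                0.05), 0.95)
      } else params$pole_fraction_mean
      y <- profile_from_pole_fraction(target, grid)
      if (noise_sd > 0) y <- y + rnorm(n_points, 0, noise_sd)
      y <- (y - min(y)) / (max(y) - min(y))
      tibble(profile_id = sprintf("prof_%04d", k),
             distance = grid, intensity = y,
             pole_fraction_true = target)
    })
  })
}
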