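#' EB1 track filter rules
#'
#' The published retention rules for automatically tracked comets: duration
#' within 2-4 s, median track quality within 200-600, and both the first and
#' the last frame index inside the video window (frames 0-30; the window is
#' exposed as a parameter).
#'
#' @param min_duration_s,max_duration_s duration window \[s\], inclusive.
#' @param quality_range numeric length-2, inclusive median-quality window.
#' @param start_end_window numeric length-2, inclusive frame-index window
#'   that must contain both track endpoints.
#' @return object of class `track_filter_rules`.
#' @export
#' @examples
#' track_filter_rules()
track_filter_rules <- function(min_duration_s = 2, max_duration_s = 4,
                               quality_range = c(200, 600),
                               start_end_window = c(0, 30)) {
  if (min_duration_s >= max_duration_s) {
    abort("`min_duration_s` must be smaller than `max_duration_s`.",
          class = "spindlescale_error_params")
  }
  stopifnot(length(quality_range) == 2, quality_range[1] < quality_range[2],
            length(start_end_window) == 2,
            start_end_window[1] <= start_end_window[2])
  structure(list(min_duration_s = min_duration_s,
                 max_duration_s = max_duration_s,
                 quality_range = quality_range,
                 start_end_window = start_end_window),
            class = "track_filter_rules")
}

# Per-track features used by the filter and the speed analytics.
track_features <- function(tracks) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "frame", "time_s", "x_um", "y_um", "quality")
                %in% names(tracks)))
  tracks %>%
    group_by(.data$track_id) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    summarise(
      cell_id = if ("cell_id" %in% names(tracks))
        .data$cell_id[1] else NA_character_,
      n_points = dplyr::n(),
      duration_s = max(.data$time_s) - min(.data$time_s),
      median_quality = median(.data$quality),
      first_frame = min(.data$frame),
      last_frame = max(.data$frame),
      path_length_um = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
      compartment = if ("compartment" %in% names(tracks))
        .data$compartment[1] else NA_character_,
      V_cell_um3 = if ("V_cell_um3" %in% names(tracks))
        .data$V_cell_um3[1] else NA_real_,
      .groups = "drop")
}

#' Filter comet tracks by the retention rules
#'
#' A track is kept iff its duration lies in the duration window, its median
#' quality in the quality window, and both endpoints in the frame window.
#' Every rejected track carries its first failing rule (`"duration"`,
#' `"quality"` or `"window"`).  Filtering is idempotent.
#'
#' @param tracks long-format track tibble (`track_id`, `frame`, `time_s`,
#'   `x_um`, `y_um`, `quality`, ...).
#' @param rules a [track_filter_rules()] object.
#' @return list with `kept` and `rejected` (both long-format tibbles;
#'   `rejected` has a `reject_reason` column) and `summary` (per-track
#'   feature tibble with `kept`/`reject_reason`).
#' @export
filter_tracks <- function(tracks, rules = track_filter_rules()) {
  stopifnot(inherits(rules, "track_filter_rules"))
  if (!nrow(tracks)) {
    return(list(kept = tracks, rejected = tracks[0, ],
                summary = tibble()))
  }
  feats <- track_features(tracks)
  reason <- rep(NA_character_, nrow(feats))
  bad_dur <- feats$duration_s < rules$min_duration_s |
    feats$duration_s > rules$max_duration_s
  bad_q <- feats$median_quality < rules$quality_range[1] |
    feats$median_quality > rules$quality_range[2]
  bad_win <- feats$first_frame < rules$start_end_window[1] |
    feats$last_frame > rules$start_end_window[2]
  reason[bad_win] <- "window"
  reason[bad_q] <- "quality"
  reason[bad_dur] <- "duration"   # first rule in the published order wins
  feats$reject_reason <- reason
  feats$kept <- is.na(reason)
  kept_ids <- feats$track_id[feats$kept]
  rejected <- tracks %>%
    filter(!.data$track_id %in% kept_ids) %>%
    left_join(select(feats, "track_id", "reject_reason"), by = "track_id")
  list(kept = filter(tracks, .data$track_id %in% kept_ids),
       rejected = rejected,
       summary = feats)
}

#' Per-cell mean comet growth speed
#'
#' Per-track speed is total path length divided by duration (comets grow
#' near-ballistically, so path length and end-to-end displacement are
#' practically equal); the per-cell value is the mean over that cell's kept
#' tracks.
#'
#' @param tracks kept long-format track tibble.
#' @return tibble with `cell_id`, `v_p_um_per_s`, `n_tracks`.
#'   Zero-duration tracks are signalled.
#' @export
mean_growth_speed <- function(tracks) {
  if (!nrow(tracks)) return(tibble(cell_id = character(0),
                                   v_p_um_per_s = numeric(0),
                                   n_tracks = integer(0)))
  feats <- track_features(tracks)
  if (any(feats$duration_s <= 0)) {
    abort("Zero-duration track: speed undefined.",
          class = "spindlescale_error_record")
  }
  feats %>%
    mutate(speed = .data$path_length_um / .data$duration_s) %>%
    group_by(.data$cell_id) %>%
    summarise(v_p_um_per_s = mean(.data$speed), n_tracks = dplyr::n(),
              .groups = "drop")
}

#' Pole share of a half-spindle intensity profile
#'
#' Percentage of the trapezoidal intensity integral falling in the pole half
#' (normalized distance 0-0.5) relative to the full profile (0-1).  The
#' profile is linearly interpolated at distance 0.5 if that grid point is
#' absent.
#'
#' @param distance,intensity profile vectors; `distance` monotone increasing
#'   in \[0, 1\].
#' @return percent in \[0, 100\].  A zero total integral is signalled.
#' @export
#' @examples
#' x <- seq(0, 1, 0.01)
#' pole_signal_fraction(x, rep(1, length(x)))  # 50
#' pole_signal_fraction(x, 1 - x)              # 75
pole_signal_fraction <- function(distance, intensity) {
  if (length(distance) != length(intensity) || length(distance) < 3) {
    abort("Profile needs >= 3 matching points.",
          class = "spindlescale_error_params")
  }
  if (is.unsorted(distance, strictly = TRUE)) {
    abort("`distance` must be strictly increasing.",
          class = "spindlescale_error_record")
  }
  if (any(intensity < 0)) {
    abort("`intensity` must be non-negative.",
          class = "spindlescale_error_record")
  }
  total <- trapz(distance, intensity)
  if (total <= 0) {
    abort("Zero total profile integral: pole fraction undefined.",
          class = "spindlescale_error_degenerate")
  }
  if (!any(distance == 0.5) && min(distance) < 0.5 && max(distance) > 0.5) {
    y_half <- approx(distance, intensity, xout = 0.5)$y
    keep <- distance <= 0.5
    xs <- c(distance[keep], 0.5); ys <- c(intensity[keep], y_half)
  } else {
    keep <- distance <= 0.5
    xs <- distance[keep]; ys <- intensity[keep]
  }
  100 * trapz(xs, ys) / total
}

#' Pole fractions for a profile table
#'
#' Applies [pole_signal_fraction()] per `profile_id`.
#'
#' @param profiles tibble with `profile_id`, `distance`, `intensity`.
#' @return tibble with `profile_id`, `pole_fraction_pct`.
#' @export
pole_signal_fractions <- function(profiles) {
  profiles %>%
    group_by(.data$profile_id) %>%
    dplyr::group_modify(~ tibble(
      pole_fraction_pct = pole_signal_fraction(.x$distance, .x$intensity))) %>%
    ungroup()
}

#' Comet compartment partition statistics for one cell
#'
#' Counts comets by compartment label at a few sample frames (averaged, as
#' in the published counting at three frames of each video), and derives the
#' astral:bulk ratio and the total comet number per unit cell volume.
#'
#' @param tracks long-format track tibble for one cell, with `compartment`.
#' @param cell_volume_um3 the cell's volume \[um^3\].
#' @param sample_frames frame indices at which comets are counted
#'   (default `c(1, 15, 30)`, inside the default track window).
#' @return one-row tibble: `astral_count`, `bulk_count`,
#'   `astral_bulk_ratio` (`NA` with `ratio_defined = FALSE` when no bulk
#'   comets), `comets_per_um3`, `n_tracks`.
#' @export
comet_partition <- function(tracks, cell_volume_um3,
                            sample_frames = c(1, 15, 30)) {
  stop_if_not_positive(cell_volume_um3, "cell_volume_um3")
  if (!nrow(tracks)) {
    return(tibble(astral_count = 0, bulk_count = 0,
                  astral_bulk_ratio = NA_real_, ratio_defined = FALSE,
                  comets_per_um3 = 0, n_tracks = 0L))
  }
  stopifnot("compartment" %in% names(tracks))
  feats <- track_features(tracks)
  counts <- purrr::map_dfr(sample_frames, function(f) {
    live <- feats[feats$first_frame <= f & feats$last_frame >= f, ]
    tibble(astral = sum(live$compartment == "astral"),
           bulk = sum(live$compartment == "bulk"))
  })
  astral <- mean(counts$astral); bulk <- mean(counts$bulk)
  tibble(astral_count = astral, bulk_count = bulk,
         astral_bulk_ratio = if (bulk > 0) astral / bulk else NA_real_,
         ratio_defined = bulk > 0,
         comets_per_um3 = (astral + bulk) / cell_volume_um3,
         n_tracks = nrow(feats))
}
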