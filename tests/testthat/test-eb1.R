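test_that("track filtering applies the published retention rules", {
  rules <- track_filter_rules()
  # 4 frames at 0.4 s = 1.6 s duration -> rejected for duration
  short <- make_track("t1", 4, frame0 = 2, quality = 400)
  res <- filter_tracks(short, rules)
  expect_equal(nrow(res$kept), 0)
  expect_equal(unique(res$rejected$reject_reason), "duration")
  # a compliant track (7 frames = 2.4 s, quality 400, inside frames 0-30)
  good <- make_track("t2", 7, frame0 = 5, quality = 400)
  expect_equal(nrow(filter_tracks(good, rules)$kept), nrow(good))
  # quality and window rejections carry their reason
  lowq <- make_track("t3", 7, frame0 = 5, quality = 100)
  expect_equal(unique(filter_tracks(lowq, rules)$rejected$reject_reason),
               "quality")
  late <- make_track("t4", 7, frame0 = 28, quality = 400)
  expect_equal(unique(filter_tracks(late, rules)$rejected$reject_reason),
               "window")
})

test_that("filter decisions agree with an exhaustive rule-by-rule oracle", {
  withr::local_seed(14)
  rules <- track_filter_rules()
  tracks <- purrr::map_dfr(1:1000, function(i) {
    n <- sample(2:14, 1)
    make_track(sprintf("tr%04d", i), n, frame0 = sample(0:30, 1),
               quality = runif(1, 0, 800))
  })
  res <- filter_tracks(tracks, rules)
  feats <- res$summary
  oracle <- oracle_keep(feats$duration_s, feats$median_quality,
                        feats$first_frame, feats$last_frame, rules)
  expect_identical(feats$kept, oracle)
  # idempotence: filtering the kept set changes nothing
  again <- filter_tracks(res$kept, rules)
  expect_identical(sort(unique(again$kept$track_id)),
                   sort(unique(res$kept$track_id)))
})

test_that("growth speed is path length over duration", {
  tr <- make_track("t1", 2, frame0 = 0, quality = 400, speed = 0.26)
  expect_equal(mean_growth_speed(tr)$v_p_um_per_s, 0.104 / 0.4)
  static <- make_track("t2", 5, frame0 = 0, quality = 400, speed = 0)
  expect_equal(mean_growth_speed(static)$v_p_um_per_s, 0)
})

test_that("growth speed is invariant under rigid motions", {
  withr::local_seed(15)
  tr <- generate_comet_tracks(state_params("ESC"), 3, 8, seed = 15)
  v0 <- mean_growth_speed(tr)
  th <- 0.83
  moved <- dplyr::mutate(tr,
    x_new = cos(th) * x_um - sin(th) * y_um + 12,
    y_new = sin(th) * x_um + cos(th) * y_um - 7,
    x_um = x_new, y_um = y_new)
  expect_equal(mean_growth_speed(moved)$v_p_um_per_s, v0$v_p_um_per_s,
               tolerance = 1e-12)
})

test_that("synthetic populations reproduce the published growth speed", {
  tr <- generate_comet_tracks(state_params("ESC"), n_cells = 92,
                              tracks_per_cell = 60, seed = 42)
  kept <- filter_tracks(tr)$kept
  per_cell <- mean_growth_speed(kept)
  expect_equal(nrow(per_cell), 92)
  sem <- sd(per_cell$v_p_um_per_s) / sqrt(nrow(per_cell))
  expect_lt(abs(mean(per_cell$v_p_um_per_s) - 0.26), 2 * sem)
})

test_that("pole signal fraction integrates the profile halves", {
  x <- seq(0, 1, 0.01)
  expect_equal(pole_signal_fraction(x, rep(1, length(x))), 50)
  expect_equal(pole_signal_fraction(x, 1 - x), 75)
  all_pole <- ifelse(x < 0.5, 1 - 2 * x, 0)
  expect_equal(pole_signal_fraction(x, all_pole), 100)
  expect_error(pole_signal_fraction(x, rep(0, length(x))),
               class = "spindlescale_error_degenerate")
  # works without a grid point at exactly 0.5
  x2 <- seq(0, 1, length.out = 90)
  expect_equal(pole_signal_fraction(x2, rep(2, 90)), 50, tolerance = 1e-9)
})

test_that("a profile and its mirror average to a 50% pole share", {
  withr::local_seed(16)
  x <- seq(0, 1, 0.01)
  for (i in 1:20) {
    y <- abs(stats::filter(runif(length(x)), rep(1 / 5, 5),
                           circular = TRUE)) + 0.05
    y <- as.numeric(y)
    f1 <- pole_signal_fraction(x, y)
    f2 <- pole_signal_fraction(x, rev(y))
    expect_equal((f1 + f2) / 2, 50, tolerance = 1e-8)
  }
})

test_that("comet partition counts compartments and handles edge cases", {
  full <- purrr::map_dfr(1:50, function(i) {
    make_track(sprintf("t%02d", i), 31, frame0 = 0, quality = 400,
               compartment = if (i <= 10) "astral" else "bulk")
  })
  cs <- comet_partition(full, cell_volume_um3 = 2000)
  expect_equal(cs$astral_count, 10)
  expect_equal(cs$bulk_count, 40)
  expect_equal(cs$astral_bulk_ratio, 0.25)
  expect_equal(cs$comets_per_um3, 0.025)
  none <- comet_partition(full[0, ], 2000)
  expect_equal(none$astral_count, 0)
  expect_false(none$ratio_defined)
  only_astral <- dplyr::mutate(full, compartment = "astral")
  expect_false(comet_partition(only_astral, 2000)$ratio_defined)
})

test_that("equal comet densities with different astral odds differ only in ratio", {
  p_lo <- state_params("ESC", astral_prob = 0.1)
  p_hi <- state_params("ESC", astral_prob = 0.4)
  stats_for <- function(p, seed) {
    tr <- generate_comet_tracks(p, 25, 40, seed = seed)
    tr %>%
      dplyr::group_by(cell_id) %>%
      dplyr::group_modify(~ comet_partition(.x, .x$V_cell_um3[1])) %>%
      dplyr::ungroup()
  }
  lo <- stats_for(p_lo, 18)
  hi <- stats_for(p_hi, 19)
  dens_test <- compare_groups(lo$comets_per_um3, hi$comets_per_um3)
  expect_gt(dens_test$p_two_sided, 0.01)
  ratio_test <- compare_groups(lo$astral_bulk_ratio, hi$astral_bulk_ratio)
  expect_lt(ratio_test$p_two_sided, 1e-4)
})
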