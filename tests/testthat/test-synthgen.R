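test_that("generators are deterministic under a fixed seed", {
  p <- state_params("ESC")
  expect_identical(generate_cell_population(p, 50, seed = 7),
                   generate_cell_population(p, 50, seed = 7))
  expect_identical(generate_frap_traces(p, 3, seed = 7),
                   generate_frap_traces(p, 3, seed = 7))
  expect_identical(generate_comet_tracks(p, 2, 5, seed = 7),
                   generate_comet_tracks(p, 2, 5, seed = 7))
  expect_identical(generate_half_spindle_profiles(p, 3, seed = 7),
                   generate_half_spindle_profiles(p, 3, seed = 7))
  expect_identical(generate_blot_dataset(noise_cv = 0.05, seed = 7),
                   generate_blot_dataset(noise_cv = 0.05, seed = 7))
  expect_identical(generate_lineages(3600, 600, 36000, 3, seed = 7),
                   generate_lineages(3600, 600, 36000, 3, seed = 7))
  # different seeds give different draws
  expect_false(identical(generate_cell_population(p, 50, seed = 7),
                         generate_cell_population(p, 50, seed = 8)))
})

test_that("truncation never yields non-positive volumes, densities or speeds", {
  withr::local_seed(11)
  for (i in 1:15) {
    p <- state_params(
      "ESC",
      cell_volume_mean = runif(1, 500, 4000),
      cell_volume_sd = runif(1, 100, 1500),
      mass_density_mean = runif(1, 50, 200),
      mass_density_sd = runif(1, 5, 60),
      scaling_noise_sd = runif(1, 0, 0.4),
      frap_t_half = runif(1, 2, 30),
      frap_t_half_sd = runif(1, 0, 15),
      comet_speed_mean = runif(1, 0.05, 0.5),
      comet_speed_sd = runif(1, 0, 0.2))
    cells <- generate_cell_population(p, 150, seed = i)
    expect_true(all(cells$V_cell_um3 > 0))
    expect_true(all(cells$V_spindle_um3 > 0))
    expect_true(all(cells$V_spindle_um3 < cells$V_cell_um3))
    expect_true(all(cells$V_centrosome_um3 > 0))
    expect_true(all(cells$V_centrosome_um3 < cells$V_spindle_um3))
    expect_true(all(cells$rho_mg_per_ml > 0))
    tr <- generate_frap_traces(p, 2, seed = i)
    expect_true(all(tr$t_half_true_s > 0))
    ct <- generate_comet_tracks(p, 2, 4, seed = i)
    expect_true(all(ct$speed_true_um_per_s > 0))
  }
})

test_that("synthetic stem-cell volumes reproduce the printed population mean", {
  cells <- generate_cell_population(state_params("ESC"), n = 1084, seed = 1)
  sem <- sd(cells$V_cell_um3) / sqrt(nrow(cells))
  expect_lt(abs(mean(cells$V_cell_um3) - 2719), 2 * sem)
})

test_that("noiseless proportional scaling gives a constant spindle fraction", {
  p <- state_params("ESC", scaling_noise_sd = 0, subscaling_factor = 0)
  cells <- generate_cell_population(p, 10, seed = 3)
  ratio <- cells$V_spindle_um3 / cells$V_cell_um3
  expect_equal(ratio, rep(ratio[1], 10), tolerance = 1e-12)
})

test_that("rank correlation of spindle and cell volume falls as scaling noise grows", {
  rs <- vapply(c(0.05, 0.225, 0.5), function(s) {
    cells <- generate_cell_population(
      state_params("ESC", scaling_noise_sd = s), 3000, seed = 5)
    spearman_rho(cells$V_cell_um3, cells$V_spindle_um3)
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("FRAP generator honours its noiseless contracts", {
  p <- state_params("ESC", frap_t_half = 11.1, frap_t_half_sd = 0)
  # no acquisition decay, no noise -> control constant
  tr <- generate_frap_traces(p, 1, seed = 1, noise_sd = 0,
                             acq_bleach_tau_s = Inf)
  expect_equal(tr$control_roi, rep(1, nrow(tr)))
  # t_half = tau * ln 2: the noiseless curve reaches half recovery at
  # t = 0.6931 s when tau = 1 s
  p2 <- state_params("ESC", frap_t_half = log(2), frap_t_half_sd = 0)
  tr2 <- generate_frap_traces(p2, 1, seed = 1, noise_sd = 0,
                              acq_bleach_tau_s = Inf,
                              amplitude = 0.6, offset = 0.2)
  post <- tr2[tr2$phase == "post", ]
  t0 <- post$time_s[1]
  curve_at <- function(t) 0.6 * (1 - exp(-(t - t0) / 1)) + 0.2
  expect_equal(curve_at(t0 + 0.6931), 0.2 + 0.3, tolerance = 1e-4)
  expect_equal(post$bleach_roi[1], 0.2, tolerance = 1e-12)
  # layout: 3 pre-bleach and 35 post-bleach frames at 1 s
  expect_equal(sum(tr$phase == "pre"), 3)
  expect_equal(sum(tr$phase == "post"), 35)
  expect_equal(diff(tr$time_s[tr$phase == "post"]), rep(1, 34))
  expect_error(generate_frap_traces(p, 1, noise_sd = -0.1),
               class = "spindlescale_error_params")
})

test_that("comet tracks move at the drawn speed and degenerate cleanly", {
  p <- state_params("ESC", comet_speed_mean = 0.26, comet_speed_sd = 0)
  tr <- generate_comet_tracks(p, 1, 1, seed = 2)
  d <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  expect_equal(d, rep(0.26 * 0.4, length(d)), tolerance = 1e-12)
  p0 <- state_params("ESC", comet_speed_mean = 0, comet_speed_sd = 0)
  tr0 <- generate_comet_tracks(p0, 1, 1, seed = 2)
  expect_equal(sd(tr0$x_um), 0)
  expect_equal(sd(tr0$y_um), 0)
})

test_that("profile generator hits its target pole fraction in expectation", {
  p <- state_params("ESC", pole_fraction_mean = 0.6, pole_fraction_sd = 0.05)
  pr <- generate_half_spindle_profiles(p, 100, seed = 9)
  rec <- pole_signal_fractions(pr)
  expect_equal(mean(rec$pole_fraction_pct) / 100, 0.6, tolerance = 0.02)
  # recovered fraction matches each profile's own generating target
  truth <- dplyr::distinct(pr, profile_id, pole_fraction_true)
  j <- dplyr::left_join(rec, truth, by = "profile_id")
  expect_lt(max(abs(j$pole_fraction_pct / 100 - j$pole_fraction_true)), 0.01)
  # axes are min-max normalized
  expect_equal(min(pr$intensity), 0)
  expect_equal(max(pr$intensity), 1)
})

test_that("lineages accumulate cycles and yield intermitotic times", {
  # deterministic cycles: 10-h cycles in a 40-h recording -> 4 divisions
  lin <- generate_lineages(10 * 3600, 0, 40 * 3600, n_families = 3, seed = 1)
  for (f in unique(lin$family_id)) {
    dt <- intermitotic_times(lin$division_time_s[lin$family_id == f])
    expect_equal(dt, rep(10 * 3600, length(dt)))
  }
  counts <- table(lin$family_id)
  expect_true(all(counts %in% 3:4))
  # recording shorter than one cycle -> empty lineage, not an error
  lin0 <- generate_lineages(10 * 3600, 0, 10 * 3600, n_families = 1, seed = 1)
  expect_true(nrow(lin0) <= 1)
  # law of large numbers on stochastic cycles
  lin2 <- generate_lineages(10 * 3600, 3600, 400 * 3600, n_families = 30,
                            seed = 2)
  ints <- unlist(lapply(split(lin2$division_time_s, lin2$family_id),
                        intermitotic_times))
  expect_lt(abs(mean(ints) - 10 * 3600), 2 * sd(ints) / sqrt(length(ints)))
})

test_that("invalid generator inputs are rejected", {
  p <- state_params("ESC")
  expect_error(generate_cell_population(p, 0), class = "spindlescale_error_params")
  expect_error(state_params("ESC", subscaling_factor = 1.2),
               class = "spindlescale_error_params")
  expect_error(state_params("ESC", pole_fraction_mean = 0),
               class = "spindlescale_error_params")
  expect_error(generate_blot_dataset(0), class = "spindlescale_error_params")
  expect_error(generate_blot_dataset(1.5, standards_ng = c(50, 50)),
               class = "spindlescale_error_params")
  expect_error(generate_lineages(10, 1, 5, 1),
               class = "spindlescale_error_params")
})
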