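test_that("volume binning follows the left-closed right-open convention", {
  edges <- seq(1000, 3500, 500)
  df <- tibble::tibble(V_cell_um3 = c(2499, 2500, 900, 3500, 1000))
  b <- bin_by_cell_volume(df, edges)
  expect_equal(b$bin, c("[2000,2500)", "[2500,3000)", "unbinned",
                        "unbinned", "[1000,1500)"))
})

test_that("binning partitions every record into exactly one bucket", {
  withr::local_seed(4)
  df <- tibble::tibble(V_cell_um3 = runif(500, 0, 5000))
  b <- bin_by_cell_volume(df, seq(1000, 3500, 500))
  expect_equal(nrow(b), 500)
  expect_true(all(!is.na(b$bin)))
  inside <- b$bin != "unbinned"
  expect_true(all(b$V_cell_um3[inside] >= b$bin_low[inside] &
                    b$V_cell_um3[inside] < b$bin_high[inside]))
  expect_true(all(b$V_cell_um3[!inside] < 1000 | b$V_cell_um3[!inside] >= 3500))
  expect_error(bin_by_cell_volume(df, c(2000, 1000)),
               class = "spindlescale_error_params")
})

test_that("Welch comparison matches the textbook-formula oracle to 1e-10", {
  withr::local_seed(21)
  for (i in 1:1000) {
    a <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- compare_groups(a, b)
    ora <- oracle_welch(a, b)
    expect_equal(got$t_statistic, ora$t, tolerance = 1e-10)
    expect_equal(got$df_welch, ora$df, tolerance = 1e-10)
    expect_equal(got$p_two_sided, ora$p, tolerance = 1e-10)
    expect_equal(got$cohens_d, ora$d, tolerance = 1e-10)
  }
})

test_that("Cohen's d and degenerate comparisons behave as defined", {
  expect_equal(compare_groups(c(1, 2, 3), c(3, 4, 5))$cohens_d, -2)
  same <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_two_sided, 1)
  expect_equal(same$cohens_d, 0)
  expect_error(compare_groups(c(1, 1), c(2, 2)),
               class = "spindlescale_error_degenerate")
})

test_that("Welch test holds its nominal type-I error rate", {
  withr::local_seed(33)
  reps <- 10000
  hits <- 0L
  for (i in seq_len(reps)) {
    a <- rnorm(50); b <- rnorm(50)
    if (compare_groups(a, b)$p_two_sided < 0.05) hits <- hits + 1L
  }
  expect_lt(abs(hits / reps - 0.05), 0.01)
})

test_that("Spearman correlation is a rank statistic", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_rho(x, x^3), 1)
  expect_equal(spearman_rho(x, -x), -1)
  # invariance under strictly monotone transforms
  withr::local_seed(5)
  for (i in 1:20) {
    u <- rnorm(30); v <- rnorm(30)
    base <- spearman_rho(u, v)
    expect_equal(spearman_rho(exp(u), v), base, tolerance = 1e-12)
    expect_equal(spearman_rho(u, v^3 + 5 * v), base, tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "spindlescale_error_degenerate")
})

test_that("subscaling profile measures the binned median deficit", {
  mk <- function(med) tibble::tibble(
    bin = "[1000,1500)", bin_low = 1000, bin_high = 1500,
    n = 50, median = med, iqr_low = med * 0.9, iqr_high = med * 1.1)
  sp <- subscaling_profile(mk(250), mk(190))
  expect_equal(sp$deficits$deficit_pct, 24)
  expect_equal(sp$max_deficit_pct, 24)
  # a population against itself is identically zero
  cells <- generate_cell_population(state_params("ESC"), 400, seed = 6)
  bs <- summarise_bins(cells, seq(1000, 3500, 500))
  self <- subscaling_profile(bs, bs)
  expect_equal(self$deficits$deficit_pct, rep(0, nrow(self$deficits)))
  # zero reference median is signalled
  expect_error(subscaling_profile(mk(0), mk(10)),
               class = "spindlescale_error_degenerate")
  # low-count bins are flagged and excluded from the maximum
  small <- mk(250); small$n <- 3
  sp2 <- subscaling_profile(small, mk(150), min_n = 5)
  expect_true(sp2$deficits$flagged)
  expect_true(is.na(sp2$max_deficit_pct))
})

test_that("occupancy and fold changes are plain ratios with guard rails", {
  expect_equal(occupancy(10, 1000), 1)
  expect_equal(occupancy(0, 1000), 0)
  expect_error(occupancy(20, 10), class = "spindlescale_error_record")
  x <- c(1, 2, 3, 4)
  expect_equal(fold_change_vs_control(x, x)$median_fold, 1)
  expect_equal(fold_change_vs_control(2 * x, x)$median_fold, 2)
  expect_error(fold_change_vs_control(x, c(-1, 1)),
               class = "spindlescale_error_degenerate")
})

test_that("hypo-osmotic dilution lowers the density fold below one", {
  iso <- generate_cell_population(state_params("ISO"), 500, seed = 8)
  hypo <- generate_cell_population(state_params("HYPO"), 500, seed = 9)
  fc <- fold_change_vs_control(hypo$rho_mg_per_ml, iso$rho_mg_per_ml)
  expect_lt(fc$median_fold, 1)
  expect_equal(fc$median_fold, 112 / 118, tolerance = 0.03)
})

test_that("intermitotic times are successive differences", {
  expect_equal(intermitotic_times(c(0, 10, 25) * 3600), c(10, 15) * 3600)
  expect_equal(intermitotic_times(5 * 3600), numeric(0))
  expect_error(intermitotic_times(c(10, 5)),
               class = "spindlescale_error_record")
})
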