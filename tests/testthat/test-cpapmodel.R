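mp <- model_params()

test_that("free tubulin follows the cellular mass balance", {
  expect_equal(free_tubulin_concentration(2719, 0, mp)$c_free, mp$c_tot)
  half <- model_params(c_tot = 2, rho_poly = 2)
  expect_equal(free_tubulin_concentration(1000, 500, half)$c_free, 1)
  # strictly decreasing in spindle volume at fixed cell volume
  vs <- seq(0, 900, 50)
  cf <- free_tubulin_concentration(rep(1000, length(vs)), vs, mp)$c_free
  expect_true(all(diff(cf) < 0))
  # mass-balance violation is clipped and flagged
  rich <- model_params(c_tot = 0.1, rho_poly = 10)
  out <- free_tubulin_concentration(1000, 900, rich)
  expect_equal(out$c_free, 0)
  expect_true(out$clipped)
  expect_error(free_tubulin_concentration(1000, 1000, mp),
               class = "spindlescale_error_record")
})

test_that("CPAP liberation follows single-site inhibition", {
  expect_equal(cpap_free_fraction(0, 0.3), 1)
  expect_equal(cpap_free_fraction(0.3, 0.3), 0.5)
  expect_lt(cpap_free_fraction(1e6 * 0.3, 0.3), 1e-5)
})

test_that("predicted astral counts saturate in cell volume", {
  f <- 0.2
  expect_equal(predict_astral_count(mp$K_V, f, mp),
               mp$alpha * mp$cpap_total * f / 2)
  expect_equal(predict_astral_count(1e9, f, mp),
               mp$alpha * mp$cpap_total * f, tolerance = 1e-6)
  expect_equal(predict_astral_count(2000, 2 * f, mp),
               2 * predict_astral_count(2000, f, mp))
  # monotone increasing and bounded for random admissible parameters
  withr::local_seed(44)
  for (i in 1:15) {
    pars <- model_params(cpap_total = runif(1, 50, 2000),
                         alpha = runif(1, 0.1, 2),
                         K_V = runif(1, 200, 4000))
    ff <- runif(1, 0.01, 1)
    v <- sort(runif(50, 100, 8000))
    n <- predict_astral_count(v, ff, pars)
    expect_true(all(diff(n) > 0))
    expect_true(all(n < pars$alpha * pars$cpap_total * ff))
  }
})

test_that("morphometric astral estimates match their book-keeping limits", {
  rec <- tibble::tibble(V_cell_um3 = c(1000, 2000),
                        V_spindle_um3 = c(mp$n_V * 1000 / mp$lambda_bulk, 0))
  est <- estimate_astral_counts(rec, mp)
  expect_equal(est$astral_estimate[1], 0)
  expect_equal(est$astral_estimate[2], mp$n_V * 2000)
  bad <- tibble::tibble(V_cell_um3 = 1000, V_spindle_um3 = 1200)
  expect_true(estimate_astral_counts(bad, mp)$inadmissible)
})

test_that("the estimator is unbiased against the generator's ground truth", {
  cells <- generate_cell_population(state_params("ESC"), 1000, seed = 52,
                                    mparams = mp)
  est <- estimate_astral_counts(cells, mp)
  diffs <- est$astral_estimate_raw - est$n_astral_true
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
})

test_that("saturation fitting recovers exact curves and flags flat ones", {
  v <- seq(1250, 3750, by = 500)
  y <- 60 * v / (1500 + v)
  f <- fit_saturation_curve(v, y)
  expect_equal(f$N_sat, 60, tolerance = 1e-6)
  expect_equal(f$K_V, 1500, tolerance = 1e-6)
  expect_length(f$flags, 0)
  flat <- fit_saturation_curve(v, rep(42, length(v)))
  expect_true("K_V_non_identifiable" %in% flat$flags)
  expect_error(fit_saturation_curve(c(1, 2), c(1, 2)),
               class = "spindlescale_error_fit")
})

test_that("saturation fit objects expose tidy, glance and autoplot", {
  v <- seq(750, 4750, by = 500)
  withr::local_seed(53)
  f <- fit_saturation_curve(v, 60 * v / (1000 + v) + rnorm(length(v), 0, 0.5),
                            count_sds = rep(0.5, length(v)))
  expect_setequal(tidy(f)$term, c("N_sat", "K_V"))
  expect_true(all(is.finite(tidy(f)$std.error)))
  expect_s3_class(autoplot(f), "ggplot")
  expect_equal(glance(f)$n_bins, length(v))
})

test_that("the mechanistic chain reduces to a Michaelis-Menten curve", {
  p <- state_params("ESC")
  V <- seq(1000, 4400, 50)
  Vs <- p$spindle_fraction * V
  cf <- free_tubulin_concentration(V, Vs, mp,
                                   c_tot = p$tubulin_mass_fraction *
                                     p$mass_density_mean)$c_free
  N <- predict_astral_count(V, cpap_free_fraction(cf, mp$K_d), mp)
  fit <- fit_saturation_curve(V, N)
  rel_rms <- sqrt(mean((N - predict_astral_count(V, fit = fit))^2)) / mean(N)
  expect_lt(rel_rms, 0.05)
})

test_that("diluted cytoplasm liberates CPAP and raises the fitted plateau", {
  esc <- state_params("ESC"); dif <- state_params("DIF")
  # at matched volumes the differentiating state has more free CPAP
  f_of <- function(p) {
    cf <- free_tubulin_concentration(
      2200, p$spindle_fraction * (1 - p$subscaling_factor) * 2200, mp,
      c_tot = p$tubulin_mass_fraction * p$mass_density_mean)$c_free
    cpap_free_fraction(cf, mp$K_d)
  }
  expect_gt(f_of(dif), f_of(esc))
  cells <- dplyr::bind_rows(
    generate_cell_population(esc, 2000, seed = 61, mparams = mp),
    generate_cell_population(dif, 2000, seed = 62, mparams = mp))
  fits <- astral_saturation_analysis(cells)
  expect_gt(fits$N_sat[fits$state == "DIF"], fits$N_sat[fits$state == "ESC"])
  # the undifferentiated curve approaches its plateau within the sampled
  # range: at the ~3,000 um^3 saturation onset the count is >= 70% of N_sat
  f_esc <- fits$fit[fits$state == "ESC"][[1]]
  expect_gt(predict_astral_count(3000, fit = f_esc) / f_esc$N_sat, 0.7)
})
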