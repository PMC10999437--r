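test_that("diapause grid candidates are confined to the tested ranges", {
  g <- diapause_grid()
  expect_equal(range(g$t_e), c(3, 10))
  expect_equal(range(g$dd_e), c(30, 130))
  expect_error(diapause_grid(t_e = seq(1, 10, 1)), "3.0-10.0")
  expect_error(diapause_grid(dd_e = seq(30, 200, 10)), "30-130")
})

test_that("the grid search is exhaustive, deterministic, and reports the true minimum", {
  m <- quick_model()
  svs <- generate_field_survey(m, weather_spec(), n_sites = 2, seed = 13)
  g <- diapause_grid(t_e = c(5.5, 6.5, 7.5), dd_e = c(100, 120, 130))
  fit1 <- calibrate_diapause(svs, m$stages, m$age_dist, grid = g)
  fit2 <- calibrate_diapause(rev(svs), m$stages, m$age_dist, grid = g)
  expect_equal(nrow(fit1$surface), 9L)
  expect_equal(coef(fit1), coef(fit2))
  expect_equal(fit1$surface$objective, fit2$surface$objective)
  expect_true(all(fit1$objective <= fit1$surface$objective + 1e-12))
  # generating pair recovered on the coarse grid
  expect_equal(unname(coef(fit1)), c(6.5, 120))
})

test_that("later diapause termination (higher dd_e) delays the late instars monotonically", {
  m <- quick_model()
  ts <- generate_temperature_series(weather_spec(seed = 19, noise_sd = 0),
                                    days = 170)
  onsets <- sapply(c(30, 80, 130), function(dd) {
    mm <- m
    mm$diapause <- diapause_params(6.5, dd)
    tr <- simulate(mm, temps = ts)
    spumaphen:::emergence_quantile_day(tr, "N3", 1)
  })
  expect_true(all(diff(onsets) > 0))
})

test_that("truth is a fixed point of the rate refinement on noiseless surveys", {
  m <- quick_model()
  svs <- generate_field_survey(m, weather_spec(), n_sites = 1,
                               noise = FALSE, seed = 23)
  # curve objective only: the weekly first-adult date is discretized, so
  # its penalty term is nonzero even at truth
  fit <- calibrate_rates(svs, m$stages, m$age_dist, m$diapause,
                         sweeps = 1, maxit_block = 40, adult_weight = 0)
  expect_identical(fit$stages, m$stages)
  expect_equal(unname(fit$objective[["final"]]),
               unname(fit$objective[["initial"]]))
})

test_that("rate refinement recovers the field parameters from a chamber start", {
  truth <- quick_model("calibrated")
  start <- spuma_preset("parameterized")
  # a cool climate keeps egg development in the 5-9 degC band, where the
  # lower egg threshold is actually identifiable from field curves
  svs <- generate_field_survey(truth, weather_spec(mean = 11),
                               n_sites = 2, site_offsets = c(0, 1),
                               noise = FALSE, seed = 5)
  fit <- calibrate_rates(svs, start$stages, truth$age_dist, truth$diapause,
                         sweeps = 2, maxit_block = 150)
  expect_lt(fit$objective[["final"]], 0.5 * fit$objective[["initial"]])
  # the egg lower threshold moves down from the chamber value of 6.5 degC,
  # and the refined egg rate at cool temperatures moves toward the truth
  expect_lt(fit$stages$egg$t_inf, 6.5)
  v_truth <- briere_rate(8, truth$stages$egg)
  expect_lt(abs(briere_rate(8, fit$stages$egg) - v_truth),
            abs(briere_rate(8, start$stages$egg) - v_truth))
})

test_that("a single uninformative date yields a flat objective surface", {
  m <- quick_model()
  ts <- generate_temperature_series(weather_spec(seed = 41), days = 80)
  sv <- structure(list(
    site = "X", year = 2017L,
    obs = data.frame(date = 66, stage = c("N3", "N4", "N5"),
                     cumulative_percent = 0),
    temps = ts, first_adult_day = NA_real_), class = "spuma_survey")
  g <- diapause_grid(t_e = c(6, 6.5, 7), dd_e = c(30, 60, 90))
  fit <- calibrate_diapause(sv, m$stages, m$age_dist, grid = g)
  expect_equal(diff(range(fit$surface$objective)), 0)
})
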