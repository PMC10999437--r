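test_that("initialization places exactly n_eggs with the Beta age profile", {
  ad <- age_distribution(5.67, 1.05)
  st <- initialize_population(100, ad, 200)
  expect_equal(sum(st$mass), 100, tolerance = 1e-12)
  expect_equal(sum(st$mass[, 2:6]), 0)
  expect_equal(st$adult_emerged, 0)

  # advanced embryonic development: ~95% of mass at age >= 0.58
  mids <- (seq_len(200) - 0.5) / 200
  expect_equal(sum(st$mass[mids >= 0.58, 1]) / 100, 0.95, tolerance = 0.01)

  # flat distribution
  stu <- initialize_population(60, age_distribution(1, 1), 100)
  expect_true(all(abs(stu$mass[, 1] - 0.6) < 1e-12))

  expect_error(age_distribution(-1, 2), "positive")
  expect_error(initialize_population(100, ad, 20), "at least 50")
})

test_that("a step conserves mass, freezes below t_inf, and enforces the CFL bound", {
  m <- quick_model()
  st <- initialize_population(100, m$age_dist, 100)

  frozen <- step_population(st, temp = 1.0, dt = 0.5, m$stages)
  expect_equal(frozen$mass, st$mass)
  expect_equal(frozen$adult_emerged, 0)

  st2 <- st
  for (i in 1:40) st2 <- step_population(st2, 25, dt = 0.04, m$stages)
  expect_equal(sum(st2$mass) + st2$adult_emerged, 100, tolerance = 1e-9)
  expect_gt(sum(st2$mass[, 2]), 0)    # some eggs hatched at 25 degC

  err <- expect_error(step_population(st, 25, dt = 1, m$stages),
                      "maximal admissible dt")
  vmax <- max(sapply(m$stages, function(p) briere_rate(25, p)))
  expect_match(conditionMessage(err), sprintf("%g", (1 / 100) / vmax),
               fixed = TRUE)
})

test_that("a point cohort crosses a stage in 1/v days (method of characteristics)", {
  m <- quick_model()
  st <- initialize_population(100, age_distribution(1, 1), 100)
  st$mass[] <- 0
  st$mass[1, 1] <- 100             # all eggs at age ~0
  v <- briere_rate(20, m$stages$egg)
  dt <- 0.04
  steps <- 0
  while (st$cum_entries[["N1"]] < 50 && steps < 5000) {
    st <- step_population(st, 20, dt, m$stages)
    steps <- steps + 1
  }
  expect_lt(steps, 5000)
  expect_lt(abs(steps * dt - 1 / v), 2 * (1 / 100) / v + dt)
})

test_that("simulated emergence matches the characteristics quantile transform", {
  m <- spuma_preset("calibrated", grid_cells = 200)
  tr <- simulate(m, temps = const_series(18, 120), bypass_diapause = TRUE)
  v1 <- briere_rate(18, m$stages$egg)
  dx <- 1 / 200
  for (q in c(0.25, 0.5, 0.75)) {
    t_pde <- spumaphen:::emergence_quantile_day(tr, "N1", 100 * q)
    t_exact <- (1 - qbeta(1 - q, m$age_dist$alpha, m$age_dist$beta)) / v1
    expect_lt(abs(t_pde - t_exact), dx / v1 + 1e-6)
  }
  # sequential stages: one cell of slack per stage traversed
  t_pde <- spumaphen:::emergence_quantile_day(tr, "N3", 50)
  t_exact <- (1 - qbeta(0.5, m$age_dist$alpha, m$age_dist$beta)) / v1 +
    1 / briere_rate(18, m$stages$n1) + 1 / briere_rate(18, m$stages$n2)
  slack <- dx * (1 / v1 + 1 / briere_rate(18, m$stages$n1) +
                   1 / briere_rate(18, m$stages$n2))
  expect_lt(abs(t_pde - t_exact), slack + 1e-6)
})

test_that("seasonal simulation conserves mass, orders stages, and converges under refinement", {
  w <- weather_spec(seed = 31)
  ts <- generate_temperature_series(w, days = 150)
  m <- quick_model()
  tr <- simulate(m, temps = ts)
  st <- tr$final_state
  expect_equal(sum(st$mass) + st$adult_emerged, 100, tolerance = 1e-6)
  # cumulative curves are non-decreasing and stagewise ordered
  expect_true(all(diff(tr$counts) >= -1e-9))
  med <- sapply(colnames(tr$percent), function(s)
    spumaphen:::emergence_quantile_day(tr, s, 50))
  expect_true(all(diff(med) >= 0))

  # halving the cell size halves the change in the 50% hatch date
  meds <- sapply(c(100, 200, 400), function(g) {
    trg <- simulate(spuma_preset("calibrated", grid_cells = g), temps = ts)
    spumaphen:::emergence_quantile_day(trg, "N1", 50)
  })
  expect_lt(abs(meds[3] - meds[2]), 0.5 * abs(meds[2] - meds[1]) + 0.02)
})

test_that("winter that never warms leaves the population dormant", {
  ts <- const_series(4, 150)
  m <- quick_model()
  expect_warning(tr <- simulate(m, temps = ts), "never met")
  expect_true(is.na(tr$termination_day))
  expect_true(all(tr$counts == 0))
})

test_that("cumulative emergence readout interpolates the stored series", {
  ts <- generate_temperature_series(weather_spec(seed = 8), days = 150)
  m <- quick_model()
  tr <- simulate(m, temps = ts)
  expect_equal(cumulative_emergence_at(tr, "N1", 10), 0)
  expect_equal(cumulative_emergence_at(tr, "N1", 150),
               unname(tr$percent[150, "N1"]))
  # midpoint reading equals manual linear interpolation
  d <- 100.5
  manual <- mean(tr$percent[c(100, 101), "N3"])
  expect_equal(cumulative_emergence_at(tr, "N3", d), manual)
  got <- cumulative_emergence_at(tr, "N4", c(70, 90, 110, 130))
  expect_true(all(diff(got) >= 0) && all(got >= 0 & got <= 100))
  expect_error(cumulative_emergence_at(tr, "egg", 100), "do not emerge")
  expect_error(cumulative_emergence_at(tr, "N1", 400), "horizon")
})

test_that("uniformly warmer forcing brings every stage forward", {
  base <- generate_temperature_series(weather_spec(noise_sd = 0), days = 160)
  warm <- temperature_series(base$temp + 2, cadence = "hourly")
  m <- quick_model()
  t1 <- simulate(m, temps = base)
  t2 <- simulate(m, temps = warm)
  for (s in c("N1", "N3", "N5")) {
    expect_lt(spumaphen:::emergence_quantile_day(t2, s, 50),
              spumaphen:::emergence_quantile_day(t1, s, 50))
  }
})
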