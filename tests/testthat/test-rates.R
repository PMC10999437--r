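test_that("Briere rate vanishes outside the thresholds and is positive inside", {
  p <- briere_params(6.5, 32, v_max = 0.0373)
  expect_equal(briere_rate(5, p), 0)
  expect_equal(briere_rate(6.5, p), 0)
  expect_equal(briere_rate(32, p), 0)
  expect_equal(briere_rate(-4, p), 0)
  expect_gt(briere_rate(20, p), 0)
  # continuous up to both endpoints from inside
  expect_lt(briere_rate(6.5 + 1e-6, p), 1e-8)
  expect_lt(briere_rate(32 - 1e-8, p), 1e-5)
  # vectorized
  expect_equal(briere_rate(c(0, 20, 40), p),
               c(0, briere_rate(20, p), 0))
})

test_that("closed-form optimum reproduces the published optima", {
  cases <- list(list(6.5, 32.0, 26.3), list(3.0, 35.0, 28.3),
                list(3.0, 33.0, 26.7), list(2.1, 33.0, 26.6))
  for (cs in cases) {
    p <- briere_params(cs[[1]], cs[[2]], a = 1e-4)
    expect_equal(round(briere_optimum(p), 1), cs[[3]])
  }
})

test_that("closed-form optimum agrees with dense grid search and the curve is unimodal", {
  set.seed(20)
  for (i in 1:30) {
    ti <- runif(1, 0, 10)
    ts <- runif(1, 25, 40)
    p <- briere_params(ti, ts, a = 1e-4)
    topt <- briere_optimum(p)
    expect_gt(topt, ti)
    expect_lt(topt, ts)
    grid <- seq(ti, ts, by = 1e-4)
    expect_lt(abs(grid[which.max(briere_rate(grid, p))] - topt), 2e-4)
    # monotone up before the optimum, down after
    up <- seq(ti, topt, length.out = 50)
    dn <- seq(topt, ts, length.out = 50)
    expect_true(all(diff(briere_rate(up, p)) >= 0))
    expect_true(all(diff(briere_rate(dn, p)) <= 0))
  }
})

test_that("scale_from_max inverts the peak rate exactly", {
  for (cs in list(c(0.0373, 6.5, 32), c(0.1747, 3, 33), c(0.2382, 3, 33))) {
    p <- briere_params(cs[2], cs[3], v_max = cs[1])
    expect_equal(briere_max_rate(p), cs[1], tolerance = 1e-9)
  }
  expect_error(scale_from_max(-1, 3, 33), "positive")
  expect_error(scale_from_max(0.1, 33, 3), "t_inf")
  expect_error(briere_params(6.5, 32), "exactly one")
  expect_error(briere_params(6.5, 32, a = 1, v_max = 1), "exactly one")
})

test_that("bundled presets carry the published stage parameters", {
  par <- spuma_preset("parameterized")
  expect_equal(briere_max_rate(par$stages$egg), 0.0373, tolerance = 1e-9)
  expect_equal(round(briere_optimum(par$stages$egg), 1), 26.3)
  expect_equal(briere_max_rate(par$stages$n2), 0.1747, tolerance = 1e-9)
  expect_equal(briere_max_rate(par$stages$n1), 0.2382, tolerance = 1e-9)

  cal <- spuma_preset("calibrated")
  expect_equal(briere_max_rate(cal$stages$egg), 0.0519, tolerance = 1e-9)
  expect_equal(round(briere_optimum(cal$stages$egg), 1), 28.3)
  expect_equal(briere_max_rate(cal$stages$n5), 0.1441, tolerance = 1e-9)
  expect_equal(cal$stages$n5$t_inf, 5.0)
  # nymphal optima stay in the published 26.6-27.0 band
  opts <- sapply(cal$stages[2:6], briere_optimum)
  expect_true(all(opts >= 26.6 - 0.05 & opts <= 27.0 + 0.05))
  expect_equal(cal$diapause$t_e, 6.5)
  expect_equal(cal$diapause$dd_e, 120)
})
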