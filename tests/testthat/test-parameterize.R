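make_chamber_from_times <- function(times, horizon = 60) {
  obs <- spumaphen:::chamber_schedule(horizon)
  data.frame(temperature_C = 24, replicate = 1L, day = rep(obs, 1),
             stage = "N1",
             cumulative_count = vapply(obs, function(d) sum(times <= d),
                                       numeric(1)))
}

test_that("Gamma emergence fit recovers a known shape from censored times", {
  set.seed(12)
  times <- rgamma(200, shape = 9, scale = 2)
  ch <- make_chamber_from_times(times)
  fit <- fit_gamma_emergence(ch, "N1", cohort = 200)
  expect_lt(abs(fit$shape - 9) / 9, 0.15)
  expect_lt(abs(fit$shape * fit$scale - 18) / 18, 0.1)

  # scale invariance: doubling all counts changes nothing
  ch2 <- ch
  ch2$cumulative_count <- 2 * ch2$cumulative_count
  fit2 <- fit_gamma_emergence(ch2, "N1", cohort = 400)
  expect_equal(fit2$shape, fit$shape, tolerance = 1e-6)
  expect_equal(fit2$scale, fit$scale, tolerance = 1e-6)
})

test_that("point-mass emergence degenerates to a near-point Gamma fit", {
  ch <- make_chamber_from_times(rep(23.5, 50))
  expect_warning(fit <- fit_gamma_emergence(ch, "N1", cohort = 50),
                 "near-point")
  expect_lt(abs(fit$shape * fit$scale - 23.5) / 23.5, 0.1)
  expect_gt(fit$shape, 50)   # tiny relative spread
})

test_that("an exact starting point is a fixed point of the chamber fit", {
  truth <- spuma_preset("parameterized")
  ch <- generate_chamber_experiment(truth$stages, truth$age_dist,
                                    analytic = TRUE)
  fit <- fit_development_params(
    ch, list(stages = truth$stages, age_dist = truth$age_dist),
    cohort = 100)
  expect_true(fit$converged)
  expect_lte(fit$objective[["final"]], 0.1)
  # parameters returned unchanged
  expect_identical(fit$stages, truth$stages)
  expect_identical(fit$age_dist, truth$age_dist)
})

test_that("blockwise fit recovers rates and the initial age interval from noiseless curves", {
  truth <- spuma_preset("parameterized")
  ch <- generate_chamber_experiment(truth$stages, truth$age_dist,
                                    analytic = TRUE)
  init <- perturbed_init()
  fit <- fit_development_params(ch, init, cohort = 100, refine = FALSE,
                                maxit_block = 300)
  expect_lt(fit$objective[["final"]], fit$objective[["initial"]])
  tv <- coef(truth)
  fv <- coef(fit)
  for (s in c("egg", "n1", "n3", "n5")) {
    expect_lt(abs(fv[paste0(s, ".t_inf")] - tv[paste0(s, ".t_inf")]), 1.0)
    expect_lt(abs(fv[paste0(s, ".t_sup")] - tv[paste0(s, ".t_sup")]), 1.0)
    expect_lt(abs(fv[paste0(s, ".v_max")] / tv[paste0(s, ".v_max")] - 1),
              0.10)
  }
  # recovered central 90% age interval close to Beta(5.67, 1.05)'s
  q_fit <- qbeta(c(0.05, 0.95), fv[["alpha"]], fv[["beta"]])
  q_tru <- qbeta(c(0.05, 0.95), 5.67, 1.05)
  expect_lt(max(abs(q_fit - q_tru)), 0.05)
})

test_that("the objective ignores replicate order and cohort rescaling", {
  truth <- spuma_preset("parameterized")
  ch <- generate_chamber_experiment(truth$stages, truth$age_dist,
                                    temps = c(18, 24), n_replicates = 3,
                                    cohort = 20, seed = 2)
  obs1 <- spumaphen:::chamber_observed(ch, cohort = 20)
  shuf <- ch[order(ch$replicate, decreasing = TRUE), ]
  attr(shuf, "cohort") <- 20
  obs2 <- spumaphen:::chamber_observed(shuf)
  expect_equal(obs1[["24"]]$pct, obs2[["24"]]$pct)
  dbl <- ch
  dbl$cumulative_count <- dbl$cumulative_count * 3
  obs3 <- spumaphen:::chamber_observed(dbl, cohort = 60)
  expect_equal(obs1[["18"]]$pct, obs3[["18"]]$pct)
})
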