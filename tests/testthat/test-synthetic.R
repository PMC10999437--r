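test_that("weather generation is a pure function of spec and seed", {
  w <- weather_spec(seed = 5)
  a <- generate_temperature_series(w, days = 20)
  b <- generate_temperature_series(w, days = 20)
  expect_identical(a$temp, b$temp)
  w2 <- weather_spec(seed = 6)
  expect_false(identical(generate_temperature_series(w2, 20)$temp, a$temp))

  flat <- weather_spec(mean = 12, annual_amp = 0, diurnal_amp = 0,
                       noise_sd = 0)
  expect_true(all(generate_temperature_series(flat, 10)$temp == 12))
  expect_error(weather_spec(annual_amp = -1), "non-negative")
})

test_that("the Mediterranean preset has a proper seasonal cycle", {
  for (sd in 1:3) {
    ts <- generate_temperature_series(weather_spec(seed = sd), days = 220)
    dm <- daily_means(ts)
    jan <- mean(dm$temp[dm$day <= 31])
    jul <- mean(dm$temp[dm$day >= 182 & dm$day <= 212])
    expect_lt(jan, jul)
  }
})

test_that("chamber cohorts develop far slower at 10 than at 24 degC and freeze below t_inf", {
  m <- spuma_preset("parameterized")
  ch <- generate_chamber_experiment(m$stages, m$age_dist,
                                    temps = c(10, 24), n_replicates = 3,
                                    cohort = 30, seed = 9)
  half_day <- function(temp) {
    d <- ch[ch$temperature_C == temp & ch$stage == "N1", ]
    tot <- tapply(d$cumulative_count, d$day, sum)
    as.numeric(names(tot))[which(tot >= 0.5 * 3 * 30)[1]]
  }
  expect_gt(half_day(10), 3 * half_day(24))

  cold <- generate_chamber_experiment(m$stages, m$age_dist, temps = 2,
                                      n_replicates = 2, cohort = 10,
                                      horizon = 60, seed = 9)
  expect_true(all(cold$cumulative_count == 0))
})

test_that("sampled chamber curves converge to the analytic characteristics CDF", {
  m <- spuma_preset("parameterized")
  big <- generate_chamber_experiment(m$stages, m$age_dist, temps = 24,
                                     n_replicates = 1, cohort = 4000,
                                     seed = 14)
  ana <- generate_chamber_experiment(m$stages, m$age_dist, temps = 24,
                                     analytic = TRUE)
  for (s in c("N1", "N3", "adult")) {
    bs <- big[big$stage == s, ]
    as_ <- ana[ana$stage == s & ana$day %in% bs$day, ]
    expect_lt(max(abs(bs$cumulative_count / 4000 -
                        as_$cumulative_count / 100)), 0.03)
  }
})

test_that("generated surveys satisfy the survey invariants by construction", {
  m <- quick_model()
  svs <- generate_field_survey(m, weather_spec(), n_sites = 3, seed = 21)
  expect_length(svs, 3L)
  for (sv in svs) {
    term <- diapause_termination_day(sv$temps, m$diapause)
    for (s in unique(sv$obs$stage)) {
      p <- sv$obs$cumulative_percent[sv$obs$stage == s]
      expect_true(all(diff(p) >= 0))
      expect_true(all(p >= 0 & p <= 100))
    }
    # stage ordering at every date: later stages never ahead
    wide <- sapply(c("N1", "N2", "N3", "N4", "N5"), function(s)
      sv$obs$cumulative_percent[sv$obs$stage == s])
    expect_true(all(apply(wide, 1, function(r) all(diff(r) <= 1e-9))))
    # nothing observed before diapause termination
    first_n1 <- sv$obs$date[sv$obs$stage == "N1" &
                              sv$obs$cumulative_percent > 0][1]
    if (!is.na(first_n1)) expect_gte(first_n1, term)
  }
})

test_that("noiseless surveys exactly interpolate the simulator and warmth shifts phenology", {
  m <- quick_model()
  svs <- generate_field_survey(m, weather_spec(noise_sd = 0), n_sites = 2,
                               site_offsets = c(0, 3), noise = FALSE,
                               seed = 33)
  sv <- svs[[1]]
  tr <- simulate(m, temps = sv$temps)
  for (s in c("N2", "N4")) {
    o <- sv$obs[sv$obs$stage == s, ]
    expect_equal(o$cumulative_percent,
                 cumulative_emergence_at(tr, s, o$date))
  }
  # +3 degC site reaches 50% N4 earlier
  d50 <- sapply(svs, function(v) {
    o <- v$obs[v$obs$stage == "N4", ]
    o$date[which(o$cumulative_percent >= 50)[1]]
  })
  expect_lt(d50[2], d50[1])
})
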