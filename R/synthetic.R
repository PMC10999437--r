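# Synthetic-data generators. No deposited field or chamber datasets exist
# for this system, so these generators produce temperature series, chamber
# cohort experiments and weekly field surveys with the statistical
# structure the model assumes; they make every estimation routine testable
# end-to-end.

#' Synthetic weather specification
#'
#' A simple sinusoidal climate: annual cycle + diurnal cycle + Gaussian
#' noise,
#' `T = mean - annual_amp * cos(2 pi day/365) + diurnal_amp * sin(2 pi hour/24) + eps`.
#' The default is a Mediterranean-like preset (annual mean 15 degC,
#' annual amplitude 8, diurnal amplitude 4, noise s.d. 1.5) matching the
#' climates in which the spittlebug populations of interest live.
#'
#' @param mean Annual mean temperature (deg C).
#' @param annual_amp Annual amplitude (deg C, >= 0).
#' @param diurnal_amp Diurnal amplitude (deg C, >= 0; ignored for daily
#'   cadence).
#' @param noise_sd Gaussian noise s.d. per sample (deg C, >= 0).
#' @param cadence `"hourly"` or `"daily"`.
#' @param seed Integer seed making the generated series reproducible.
#' @return An object of class `"weather_spec"`.
#' @export
weather_spec <- function(mean = 15, annual_amp = 8, diurnal_amp = 4,
                         noise_sd = 1.5, cadence = c("hourly", "daily"),
                         seed = NULL) {
  cadence <- match.arg(cadence)
  if (annual_amp < 0 || diurnal_amp < 0) stop("amplitudes must be non-negative")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  structure(list(mean = mean, annual_amp = annual_amp,
                 diurnal_amp = diurnal_amp, noise_sd = noise_sd,
                 cadence = cadence, seed = seed),
            class = "weather_spec")
}

# Evaluate user code with a locally seeded RNG, restoring the caller's
# RNG state afterwards. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic temperature series
#'
#' @param spec A [weather_spec()].
#' @param days Number of days to generate (>= 1).
#' @param start_day Julian day of the first sample (default 1).
#' @return A [temperature_series()].
#' @examples
#' ts <- generate_temperature_series(weather_spec(seed = 7), days = 30)
#' @export
generate_temperature_series <- function(spec, days, start_day = 1L) {
  stopifnot(inherits(spec, "weather_spec"))
  days <- as.integer(days)
  if (days < 1L) stop("'days' must be at least 1")
  with_seed(spec$seed, {
    d <- seq.int(start_day, start_day + days - 1L)
    if (spec$cadence == "hourly") {
      day_rep <- rep(d, each = 24L)
      hour <- rep(0:23, times = days)
      base <- spec$mean - spec$annual_amp * cos(2 * pi * day_rep / 365) +
        spec$diurnal_amp * sin(2 * pi * hour / 24)
    } else {
      base <- spec$mean - spec$annual_amp * cos(2 * pi * d / 365)
    }
    temperature_series(base + stats::rnorm(length(base), 0, spec$noise_sd),
                       cadence = spec$cadence, start_day = start_day)
  })
}

# thrice-weekly observation schedule (Mon/Wed/Fri pattern), days since
# experiment start
chamber_schedule <- function(horizon) {
  sort(unique(c(seq(2, horizon, 7), seq(4, horizon, 7), seq(6, horizon, 7))))
}

#' Generate a synthetic climatic-chamber experiment
#'
#' Emulates the constant-temperature cohort design used to parameterize
#' the model: cohorts of post-storage eggs reared at constant temperatures
#' (default 10/18/24/30 degC, nine replicates each), censused three times a
#' week. Individual stage-entry times are drawn from the exact
#' characteristics solution (Beta-distributed initial ages transported at
#' the Briere velocities), which keeps the generator independent of the
#' gridded solver. With `analytic = TRUE` the infinite-cohort expectation
#' is returned instead (no sampling noise; `cumulative_count` is then the
#' expected count out of a nominal cohort of 100).
#'
#' @param stages A [stage_param_set()] (the generating truth).
#' @param age_dist An [age_distribution()].
#' @param temps Chamber temperatures (deg C).
#' @param n_replicates Replicates per temperature (default 9).
#' @param cohort Eggs per replicate (default 25).
#' @param horizon Observation horizon in days; a named vector per
#'   temperature or a single number. Default 250 days at 10 degC and
#'   80 days otherwise (slow development at 10 degC needs the longer
#'   window).
#' @param seed Integer seed.
#' @param analytic If `TRUE`, return exact expected curves (no sampling).
#' @return A data frame with columns `temperature_C`, `replicate`, `day`,
#'   `stage`, `cumulative_count` (class `"spuma_chamber"`); attribute
#'   `cohort` records the per-replicate cohort size (100 for analytic
#'   mode).
#' @export
generate_chamber_experiment <- function(stages, age_dist,
                                        temps = c(10, 18, 24, 30),
                                        n_replicates = 9, cohort = 25,
                                        horizon = NULL, seed = NULL,
                                        analytic = FALSE) {
  stopifnot(inherits(stages, "stage_params"), inherits(age_dist, "age_dist"))
  if (is.null(horizon))
    horizon <- ifelse(temps <= 12, 250, 80)
  horizon <- rep_len(horizon, length(temps))
  gen <- function() {
    out <- vector("list", 0L)
    for (ti in seq_along(temps)) {
      Tc <- temps[ti]
      obs_days <- chamber_schedule(horizon[ti])
      if (analytic) {
        for (s in 2:7) {
          pct <- characteristics_curve(stages, age_dist, Tc, s, obs_days)
          out[[length(out) + 1L]] <- data.frame(
            temperature_C = Tc, replicate = 1L, day = obs_days,
            stage = stage_names[s], cumulative_count = pct)
        }
      } else {
        for (r in seq_len(n_replicates)) {
          x0 <- stats::rbeta(cohort, age_dist$alpha, age_dist$beta)
          et <- characteristics_entry_times(x0, stages, Tc)
          for (s in 2:7) {
            cnt <- vapply(obs_days, function(d) sum(et[, s - 1L] <= d),
                          numeric(1))
            out[[length(out) + 1L]] <- data.frame(
              temperature_C = Tc, replicate = r, day = obs_days,
              stage = stage_names[s], cumulative_count = cnt)
          }
        }
      }
    }
    do.call(rbind, out)
  }
  res <- with_seed(seed, gen())
  structure(res, cohort = if (analytic) 100 else cohort,
            class = c("spuma_chamber", "data.frame"))
}

#' Generate synthetic field surveys
#'
#' Emulates weekly spittlebug surveys on herbaceous cover (early March to
#' late May): the full forward model (diapause + stage transport) is run
#' on generated weather for each site, cumulative emergence is read on the
#' weekly sampling dates, and binomial observation noise for a cohort of
#' `cohort` individuals is added. Noise is coupled across dates and stages
#' (one latent uniform per cohort member), so each observed cumulative
#' curve is non-decreasing and stage-ordered by construction while each
#' single count remains Binomial(cohort, p).
#'
#' @param model A [phenology_model()] holding the generating truth
#'   (rates, diapause rule, initial age distribution).
#' @param weather A [weather_spec()]; per-site mean offsets
#'   `site_offsets` shift its annual mean.
#' @param n_sites Number of site-years (default 4).
#' @param site_offsets Additive shifts of the annual mean per site
#'   (deg C); default `-1, 0, 1, 2, ...` degrees across sites.
#' @param sampling_days Julian sampling days (default weekly, day 63 to
#'   147: early March to late May).
#' @param cohort Cohort size behind the binomial observation noise
#'   (default 100).
#' @param noise If `FALSE`, surveys exactly interpolate the simulated
#'   curves.
#' @param seed Integer seed.
#' @return A list of `"spuma_survey"` objects, each with fields `site`,
#'   `year`, `obs` (data frame `date`, `stage`, `cumulative_percent`),
#'   `temps` (the site's [temperature_series()]) and `first_adult_day`.
#' @export
generate_field_survey <- function(model, weather, n_sites = 4,
                                  site_offsets = seq_len(n_sites) - 2,
                                  sampling_days = seq(63, 147, by = 7),
                                  cohort = 100, noise = TRUE, seed = NULL) {
  stopifnot(inherits(model, "spuma_model"), inherits(weather, "weather_spec"))
  site_offsets <- rep_len(site_offsets, n_sites)
  days_needed <- max(sampling_days) + 7L
  with_seed(seed, {
    lapply(seq_len(n_sites), function(i) {
      spec_i <- weather
      spec_i$mean <- weather$mean + site_offsets[i]
      spec_i$seed <- NULL                       # draw from the live stream
      ts <- generate_temperature_series(spec_i, days = days_needed)
      tr <- simulate(model, temps = ts, horizon = days_needed)
      p <- sapply(stage_names[2:7], function(s)
        cumulative_emergence_at(tr, s, sampling_days) / 100)
      if (noise) {
        u <- stats::runif(cohort)
        pct <- apply(p, 2, function(col)
          vapply(col, function(pp) 100 * sum(u <= pp) / cohort, numeric(1)))
      } else {
        pct <- 100 * p
      }
      adult_hit <- which(pct[, "adult"] >= 1)
      obs <- data.frame(
        date = rep(sampling_days, 5L),
        stage = rep(stage_names[2:6], each = length(sampling_days)),
        cumulative_percent = as.vector(pct[, 1:5]))
      structure(list(site = paste0("S", i), year = 2016L + (i - 1L) %% 2L,
                     obs = obs, temps = ts,
                     first_adult_day = if (length(adult_hit))
                       sampling_days[adult_hit[1L]] else NA_real_),
                class = "spuma_survey")
    })
  })
}

#' @export
print.spuma_survey <- function(x, ...) {
  cat(sprintf("Field survey %s (%d): %d dates, stages %s; first adults: %s\n",
              x$site, x$year, length(unique(x$obs$date)),
              paste(unique(x$obs$stage), collapse = ","),
              ifelse(is.na(x$first_adult_day), "not seen",
                     paste("day", x$first_adult_day))))
  invisible(x)
}
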