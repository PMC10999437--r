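# File interfaces: temperature/chamber/survey CSV dialects, YAML parameter
# configs, trajectory export, and goodness-of-fit metrics.

# vectorised ISO-8601 parsing; failures become NA rather than errors
parse_stamps <- function(x, tz) {
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = tz)
  for (f in fmts) {
    na <- is.na(out)
    if (!any(na)) break
    out[na] <- as.POSIXct(strptime(x[na], f, tz = tz))
  }
  out
}

require_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

#' Read an air-temperature CSV
#'
#' Expects columns `timestamp` (ISO-8601) and `temperature` (deg C),
#' regularly sampled. Hourly vs daily cadence is auto-detected from the
#' median spacing; gaps or irregular spacing are rejected with the
#' offending interval named. Times are converted to Julian days of the
#' first timestamp's year.
#'
#' @param path CSV file path.
#' @param tz Time zone used to parse timestamps (default UTC).
#' @return A [temperature_series()].
#' @export
read_temperature_csv <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("timestamp", "temperature"), basename(path))
  tt <- parse_stamps(df$timestamp, tz)
  if (anyNA(tt)) {
    bad <- which(is.na(tt))[1L]
    stop(basename(path), " line ", bad + 1L, ": unparseable timestamp '",
         df$timestamp[bad], "'", call. = FALSE)
  }
  if (anyNA(df$temperature)) {
    bad <- which(is.na(df$temperature))[1L]
    stop(basename(path), " line ", bad + 1L, ": missing temperature",
         call. = FALSE)
  }
  steps <- diff(as.numeric(tt)) / 3600
  if (!length(steps)) stop("need at least two samples")
  cadence <- if (abs(stats::median(steps) - 1) < 1e-6) "hourly"
             else if (abs(stats::median(steps) - 24) < 1e-6) "daily"
             else stop("unsupported cadence: median spacing ",
                       stats::median(steps), " h", call. = FALSE)
  off <- which(abs(steps - stats::median(steps)) > 1e-6)
  if (length(off))
    stop(basename(path), ": irregular spacing between ",
         df$timestamp[off[1L]], " and ", df$timestamp[off[1L] + 1L],
         call. = FALSE)
  jan1 <- as.POSIXct(format(tt[1L], "%Y-01-01"), tz = tz)
  t0 <- as.numeric(difftime(tt[1L], jan1, units = "days"))
  temperature_series(df$temperature, cadence = cadence,
                     start_day = as.integer(floor(t0 + 1e-9)) + 1L)
}

#' Write a temperature series to CSV
#'
#' @param temps A [temperature_series()].
#' @param path Output path.
#' @param year Calendar year used to render timestamps (default 2017, a
#'   non-leap year consistent with the Julian-day convention).
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(temps, path, year = 2017) {
  stopifnot(inherits(temps, "spuma_temps"))
  jan1 <- as.POSIXct(paste0(year, "-01-01 00:00:00"), tz = "UTC")
  tt <- if (attr(temps, "cadence") == "hourly") temps$time
        else floor(temps$time)
  stamps <- format(jan1 + tt * 86400, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(data.frame(timestamp = stamps,
                              temperature = temps$temp),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write chamber cohort CSV
#'
#' Columns: `temperature_C`, `replicate`, `day`, `stage`,
#' `cumulative_count`. Per-replicate cumulative counts must be
#' non-decreasing in time for every stage.
#'
#' @param path CSV file path.
#' @param cohort Optional per-replicate cohort size stored as an
#'   attribute.
#' @return A `"spuma_chamber"` data frame.
#' @export
read_chamber_csv <- function(path, cohort = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("temperature_C", "replicate", "day", "stage",
                        "cumulative_count"), basename(path))
  if (!nrow(df)) stop(basename(path), " contains no observations",
                      call. = FALSE)
  for (key in split(seq_len(nrow(df)),
                    interaction(df$temperature_C, df$replicate, df$stage,
                                drop = TRUE))) {
    o <- key[order(df$day[key])]
    if (is.unsorted(df$cumulative_count[o]))
      stop(basename(path), ": cumulative counts decrease for stage ",
           df$stage[o[1L]], " at ", df$temperature_C[o[1L]],
           " degC, replicate ", df$replicate[o[1L]], call. = FALSE)
  }
  structure(df, cohort = cohort, class = c("spuma_chamber", "data.frame"))
}

#' @rdname read_chamber_csv
#' @param chamber A `"spuma_chamber"` data frame.
#' @export
write_chamber_csv <- function(chamber, path) {
  utils::write.csv(as.data.frame(chamber)[, c("temperature_C", "replicate",
                                              "day", "stage",
                                              "cumulative_count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write field-survey CSV
#'
#' Survey columns: `site`, `year`, `date` (Julian day), `stage`,
#' `cumulative_percent`; each (site, year) block becomes one survey,
#' paired with the supplied temperature series.
#'
#' @param path CSV file path.
#' @param temps A [temperature_series()] shared by all surveys, or a named
#'   list keyed by `"site.year"`.
#' @param first_adult Optional named numeric vector of first-adult Julian
#'   days keyed by `"site.year"`.
#' @return A list of `"spuma_survey"` objects.
#' @export
read_survey_csv <- function(path, temps, first_adult = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("site", "year", "date", "stage",
                        "cumulative_percent"), basename(path))
  lapply(split(df, interaction(df$site, df$year, drop = TRUE)),
         function(d) {
    key <- paste(d$site[1L], d$year[1L], sep = ".")
    ts <- if (inherits(temps, "spuma_temps")) temps else temps[[key]]
    if (is.null(ts)) stop("no temperature series for survey ", key)
    structure(list(site = d$site[1L], year = d$year[1L],
                   obs = d[, c("date", "stage", "cumulative_percent")],
                   temps = ts,
                   first_adult_day = if (!is.null(first_adult))
                     unname(first_adult[key]) else NA_real_),
              class = "spuma_survey")
  })
}

#' @rdname read_survey_csv
#' @param surveys List of `"spuma_survey"` objects.
#' @export
write_survey_csv <- function(surveys, path) {
  surveys <- survey_check(surveys)
  rows <- do.call(rbind, lapply(surveys, function(s)
    cbind(site = s$site, year = s$year, s$obs)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated trajectory to CSV
#'
#' Long format: `julian_day`, `stage`, `cumulative_count`,
#' `cumulative_percent`.
#'
#' @param traj A `"spuma_traj"` object.
#' @param path Output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "spuma_traj"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write a model parameter config (YAML)
#'
#' Structured-text serialization of a full parameter set: per-stage
#' Briere triples (either `a` or `v_max` may be given; `v_max` is
#' converted with [scale_from_max()] at load), the diapause pair, the
#' Beta age distribution, and optional numerical settings (`n_eggs`,
#' `grid_cells`, `cfl`, `diffusivity`).
#'
#' @param path YAML file path.
#' @return A [phenology_model()].
#' @export
read_params_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("stages", "diapause", "age")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop(basename(path), " is missing section(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sn <- c("egg", "n1", "n2", "n3", "n4", "n5")
  if (!all(sn %in% names(cfg$stages)))
    stop("config must define stages: ", paste(sn, collapse = ", "))
  st <- lapply(cfg$stages[sn], function(s)
    briere_params(s$t_inf, s$t_sup, a = s$a, v_max = s$v_max))
  phenology_model(
    do.call(stage_param_set, st),
    diapause_params(cfg$diapause$t_e, cfg$diapause$dd_e),
    age_distribution(cfg$age$alpha, cfg$age$beta),
    n_eggs = cfg$n_eggs %||% 100,
    grid_cells = cfg$grid_cells %||% 200L,
    cfl = cfg$cfl %||% 1,
    diffusivity = cfg$diffusivity %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_params_yaml
#' @param model A [phenology_model()].
#' @export
write_params_yaml <- function(model, path) {
  stopifnot(inherits(model, "spuma_model"))
  cfg <- list(
    stages = lapply(model$stages, function(p)
      list(t_inf = p$t_inf, t_sup = p$t_sup, a = p$a)),
    diapause = list(t_e = model$diapause$t_e, dd_e = model$diapause$dd_e),
    age = list(alpha = model$age_dist$alpha, beta = model$age_dist$beta),
    n_eggs = model$n_eggs, grid_cells = model$grid_cells, cfl = model$cfl,
    diffusivity = model$diffusivity)
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' Goodness of fit of a simulated trajectory against a survey
#'
#' Per-stage RMSE and MAE between observed and simulated cumulative
#' emergence (%), plus the onset-date error: simulated minus observed day
#' of first (1%) emergence. The observation is the reference; the metrics
#' are not symmetric in their arguments.
#'
#' @param traj A `"spuma_traj"` object.
#' @param survey A `"spuma_survey"` object with dates inside the
#'   trajectory range.
#' @return A data frame with one row per observed stage: `stage`, `rmse`,
#'   `mae`, `onset_error_days` (NA when either side never reaches 1%).
#' @export
evaluate_fit <- function(traj, survey) {
  stopifnot(inherits(traj, "spuma_traj"), inherits(survey, "spuma_survey"))
  rng <- range(traj$day)
  dates <- unique(survey$obs$date)
  if (!any(dates >= rng[1L] & dates <= rng[2L]))
    stop("no overlap between survey dates and the trajectory range")
  out <- lapply(unique(survey$obs$stage), function(s) {
    o <- survey$obs[survey$obs$stage == s, , drop = FALSE]
    pred <- cumulative_emergence_at(traj, s, o$date)
    err <- pred - o$cumulative_percent
    onset_obs <- if (max(o$cumulative_percent) >= 1) {
      k <- which(o$cumulative_percent >= 1)[1L]
      if (k == 1L) o$date[1L]
      else o$date[k - 1L] + (1 - o$cumulative_percent[k - 1L]) /
        (o$cumulative_percent[k] - o$cumulative_percent[k - 1L]) *
        (o$date[k] - o$date[k - 1L])
    } else NA_real_
    onset_sim <- emergence_quantile_day(traj, s, 1)
    data.frame(stage = s, rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
               onset_error_days = onset_sim - onset_obs)
  })
  do.call(rbind, out)
}
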