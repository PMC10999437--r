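#' Regularly sampled air-temperature series
#'
#' The forcing for every rate in the model. Internally time is measured in
#' days since 1 January 00:00 of the simulated year, so Julian day `d`
#' spans the interval `[d - 1, d)`. Hourly series store one value per hour
#' (hour `h` of day `d` at time `d - 1 + h/24`); daily series store one
#' daily mean per day (placed at midday).
#'
#' @param temp Numeric vector of air temperatures (deg C), no missing
#'   values.
#' @param cadence `"hourly"` or `"daily"`.
#' @param start_day Julian day of the first sample (default 1 = Jan 1).
#' @return An object of class `"spuma_temps"`: a data frame with columns
#'   `time` (days) and `temp`, attributes `cadence` and `start_day`.
#' @examples
#' ts <- temperature_series(rep(12, 48), cadence = "hourly")
#' daily_means(ts)
#' @export
temperature_series <- function(temp, cadence = c("hourly", "daily"),
                               start_day = 1L) {
  cadence <- match.arg(cadence)
  if (anyNA(temp)) stop("temperature series must not contain missing values")
  if (!length(temp)) stop("empty temperature series")
  n <- length(temp)
  time <- if (cadence == "hourly")
    (start_day - 1) + (seq_len(n) - 1L) / 24
  else
    (start_day - 1) + (seq_len(n) - 1L) + 0.5
  structure(data.frame(time = time, temp = temp),
            cadence = cadence, start_day = as.integer(start_day),
            class = c("spuma_temps", "data.frame"))
}

#' @export
print.spuma_temps <- function(x, ...) {
  cat(sprintf("Temperature series: %d %s samples, days %d-%d, %.1f to %.1f degC\n",
              nrow(x), attr(x, "cadence"), attr(x, "start_day"),
              last_covered_day(x), min(x$temp), max(x$temp)))
  invisible(x)
}

# Last Julian day fully covered by the series.
last_covered_day <- function(temps) {
  if (attr(temps, "cadence") == "hourly")
    as.integer(floor(max(temps$time) + 1 / 24 + 1e-9))
  else
    as.integer(floor(max(temps$time) + 0.5 + 1e-9))
}

#' Daily mean temperatures
#'
#' Averages an hourly series per calendar day (daily series are returned
#' as-is). Only complete days enter degree-day sums.
#'
#' @param temps A [temperature_series()].
#' @return Data frame with columns `day` (Julian) and `temp` (deg C).
#' @export
daily_means <- function(temps) {
  stopifnot(inherits(temps, "spuma_temps"))
  if (attr(temps, "cadence") == "daily")
    return(data.frame(day = as.integer(floor(temps$time) + 1L),
                      temp = temps$temp))
  day <- as.integer(floor(temps$time + 1e-9) + 1L)
  agg <- tapply(temps$temp, day, mean)
  n <- tapply(temps$temp, day, length)
  keep <- n == 24L
  data.frame(day = as.integer(names(agg))[keep],
             temp = as.numeric(agg)[keep])
}

# Temperature at arbitrary times (days). Hourly series are linearly
# interpolated; daily series are held constant within each day.
temp_at <- function(temps, t) {
  if (attr(temps, "cadence") == "hourly") {
    stats::approx(temps$time, temps$temp, xout = t, rule = 2)$y
  } else {
    dm <- daily_means(temps)
    idx <- pmin(pmax(floor(t) + 1L, dm$day[1L]), dm$day[nrow(dm)])
    dm$temp[match(idx, dm$day)]
  }
}
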