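#' Egg diapause-termination parameters
#'
#' Overwintering eggs resume development once they have accumulated
#' `dd_e` degree-days above the threshold temperature `t_e`, counting from
#' 1 January. The calibrated values for Italian populations are
#' `t_e = 6.5` degC and `dd_e = 120` DD.
#'
#' @param t_e Threshold temperature (deg C).
#' @param dd_e Required cumulative degree-days (deg C day, >= 0).
#' @return An object of class `"diapause_params"`.
#' @export
diapause_params <- function(t_e, dd_e) {
  stopifnot(is.numeric(t_e), length(t_e) == 1L,
            is.numeric(dd_e), length(dd_e) == 1L)
  if (dd_e < 0) stop("'dd_e' must be non-negative")
  structure(list(t_e = t_e, dd_e = dd_e), class = "diapause_params")
}

#' @export
print.diapause_params <- function(x, ...) {
  cat(sprintf("Diapause termination: %g DD above %g degC (from Jan 1)\n",
              x$dd_e, x$t_e))
  invisible(x)
}

#' Cumulative degree-days above a threshold
#'
#' Running sum, over calendar days `d >= from_day`, of
#' `max(0, mean_d - t_e)` where `mean_d` is the daily mean temperature.
#' Hourly input is averaged per calendar day first. An hourly accumulation
#' variant (`method = "hourly"`, `sum(max(0, T_h - t_e))/24`) is provided
#' for sensitivity checks.
#'
#' @param temps A [temperature_series()].
#' @param t_e Threshold temperature (deg C).
#' @param from_day First Julian day of accumulation (default 1).
#' @param method `"daily_mean"` (default) or `"hourly"`.
#' @return Data frame with columns `day` and `cum_dd` (non-decreasing).
#' @examples
#' ts <- temperature_series(rep(10.5, 10), cadence = "daily")
#' tail(degree_days(ts, t_e = 6.5), 1)  # 10 x 4 = 40 DD
#' @export
degree_days <- function(temps, t_e, from_day = 1L,
                        method = c("daily_mean", "hourly")) {
  stopifnot(inherits(temps, "spuma_temps"))
  method <- match.arg(method)
  if (method == "hourly" && attr(temps, "cadence") == "hourly") {
    day <- as.integer(floor(temps$time + 1e-9) + 1L)
    excess <- tapply(pmax(0, temps$temp - t_e), day, sum) / 24
    n <- tapply(temps$temp, day, length)
    dd <- data.frame(day = as.integer(names(excess))[n == 24L],
                     excess = as.numeric(excess)[n == 24L])
  } else {
    dm <- daily_means(temps)
    dd <- data.frame(day = dm$day, excess = pmax(0, dm$temp - t_e))
  }
  dd <- dd[dd$day >= from_day, , drop = FALSE]
  if (!nrow(dd)) stop("temperature series does not cover day ", from_day)
  gaps <- which(diff(dd$day) != 1L)
  if (length(gaps))
    stop(sprintf("temperature series has a gap between day %d and day %d",
                 dd$day[gaps[1L]], dd$day[gaps[1L] + 1L]))
  data.frame(day = dd$day, cum_dd = cumsum(dd$excess))
}

#' Day of egg diapause termination
#'
#' First Julian day on which the cumulative degree-days above `t_e`
#' (accumulated from `start`, normally 1 January) reach `dd_e`. All
#' diapausing eggs terminate together on that day, and development begins
#' on the termination day itself.
#'
#' @param temps A [temperature_series()].
#' @param params A [diapause_params()] object.
#' @param start First day of accumulation (default 1 = Jan 1).
#' @return The termination day (integer Julian day), or `NA_integer_` if
#'   the requirement is not met within the series ("not reached" is a
#'   result, not an error).
#' @examples
#' ts <- temperature_series(rep(10.5, 40), cadence = "daily")
#' diapause_termination_day(ts, diapause_params(6.5, 120))  # day 30
#' @export
diapause_termination_day <- function(temps, params, start = 1L) {
  stopifnot(inherits(params, "diapause_params"))
  dd <- degree_days(temps, params$t_e, from_day = start)
  hit <- which(dd$cum_dd >= params$dd_e)
  if (!length(hit)) return(NA_integer_)
  dd$day[hit[1L]]
}
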