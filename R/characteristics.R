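# Exact (method-of-characteristics) solution of the pure-advection stage
# model. Because the development velocity depends on time only (through
# temperature), not on age, each individual's trajectory is integrable in
# closed form: an egg of initial age x0 hatches at the time t solving
# integral(v_egg) = 1 - x0, then traverses each instar j in the time it
# takes integral(v_j) to accumulate 1. These routines are used both as an
# independent oracle for the gridded solver and as the exact engine for
# constant-temperature chamber fits.

#' Exact cumulative emergence by characteristics
#'
#' Computes, without any age grid, the fraction of the initial cohort that
#' has entered a given stage by each requested date, for development
#' starting at time `t0` (days) under the forcing `temps`. Diapause is not
#' handled here; `t0` should be the development start (e.g. the diapause
#' termination day minus one, or 0 for chamber cohorts).
#'
#' @param stages A [stage_param_set()].
#' @param age_dist An [age_distribution()].
#' @param temps A [temperature_series()], or a single number for constant
#'   temperature.
#' @param stage Target stage, index 2..7 or name.
#' @param dates Julian days (or days since start for constant temperature).
#' @param t0 Development start time (days, default 0).
#' @param resolution Quadrature step (days) for time-varying forcing
#'   (default 1/24).
#' @return Cumulative emergence percentages at `dates`.
#' @export
characteristics_curve <- function(stages, age_dist, temps, stage, dates,
                                  t0 = 0, resolution = 1 / 24) {
  stopifnot(inherits(stages, "stage_params"), inherits(age_dist, "age_dist"))
  k <- match_stage(stage)
  if (k < 2L) stop("target stage must be 2..7")

  if (is.numeric(temps) && !inherits(temps, "spuma_temps")) {
    # constant temperature: closed form
    v <- vapply(stages, function(p) briere_rate(temps, p), numeric(1))
    offset <- if (k > 2L) sum(1 / v[2:(k - 1L)]) else 0
    avail <- (dates - t0) - offset          # time available for egg devel.
    x_star <- if (v[1L] > 0) 1 - v[1L] * pmax(avail, 0)
              else rep(1, length(avail))
    x_star[avail <= 0] <- 1
    return(100 * (1 - stats::pbeta(pmin(pmax(x_star, 0), 1),
                                   age_dist$alpha, age_dist$beta)))
  }

  tmax <- max(dates)
  grid <- seq(t0, tmax + resolution, by = resolution)
  tk <- temp_at(temps, grid - resolution / 2)[-1L]   # midpoint rule
  Vfun <- lapply(stages, function(p) {
    V <- c(0, cumsum(briere_rate(tk, p) * resolution))
    list(t = grid, V = V)
  })
  Vat <- function(j, t) stats::approx(Vfun[[j]]$t, Vfun[[j]]$V, xout = t,
                                      rule = 2)$y
  Vinv <- function(j, y) {
    # earliest time at which the cumulative development reaches y;
    # -Inf marks "already satisfied at t0", +Inf "never within horizon"
    out <- rep(Inf, length(y))
    out[y <= 0] <- -Inf
    Vj <- Vfun[[j]]
    # break exact ties (flat stretches where v = 0) so the inverse is
    # single-valued, biased to the earliest time
    Vmono <- Vj$V + seq_along(Vj$V) * 1e-12
    ok <- y > 0 & y <= max(Vj$V)
    if (any(ok))
      out[ok] <- stats::approx(Vmono, Vj$t, xout = y[ok], ties = "ordered",
                               rule = 2)$y
    out
  }
  w <- pmin(dates, tmax)
  if (k > 2L) for (j in seq(k - 1L, 2L)) w <- Vinv(j, Vat(j, w) - 1)
  x_star <- 1 - Vat(1L, pmax(w, t0))
  x_star[!is.finite(w) & w > 0] <- 1           # +Inf: cannot reach stage
  100 * (1 - stats::pbeta(pmin(pmax(x_star, 0), 1),
                          age_dist$alpha, age_dist$beta))
}

#' Exact stage-entry times for sampled individuals
#'
#' For individuals with given initial egg ages, returns the times (days
#' since development start) at which each enters stages 2..7, under
#' constant temperature. Individuals that can never complete a stage (rate
#' zero at that temperature) get `Inf`.
#'
#' @param x0 Initial physiological ages in `[0, 1]`.
#' @param stages A [stage_param_set()].
#' @param temp Constant temperature (deg C).
#' @return Matrix `length(x0)` x 6 (columns N1..N5, adult) of entry times.
#' @export
characteristics_entry_times <- function(x0, stages, temp) {
  v <- vapply(stages, function(p) briere_rate(temp, p), numeric(1))
  hatch <- if (v[1L] > 0) (1 - x0) / v[1L] else rep(Inf, length(x0))
  dur <- ifelse(v[-1L] > 0, 1 / v[-1L], Inf)
  out <- outer(hatch, c(0, cumsum(dur)), `+`)
  colnames(out) <- stage_names[2:7]
  out
}
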