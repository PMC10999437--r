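# Two-step field calibration: (i) refine the stage rate functions against
# field emergence curves, (ii) exhaustive grid search for the diapause
# thresholds (Te, DDe) on the late-instar curves.

survey_check <- function(surveys) {
  if (inherits(surveys, "spuma_survey")) surveys <- list(surveys)
  ok <- vapply(surveys, inherits, logical(1), what = "spuma_survey")
  if (!length(surveys) || !all(ok))
    stop("'surveys' must be a list of 'spuma_survey' objects")
  surveys
}

# Sum of squared differences between observed and simulated cumulative
# emergence (%) across surveys; optionally restricted to a stage subset
# and extended with the half-weighted first-adult onset penalty.
survey_objective <- function(surveys, stages, age_dist, diapause,
                             stage_set = stage_names[2:6],
                             adult_weight = 0, grid_cells = 100L) {
  total <- 0
  for (sv in surveys) {
    horizon <- last_covered_day(sv$temps)
    m <- phenology_model(stages, diapause, age_dist,
                         grid_cells = grid_cells)
    tr <- simulate(m, temps = sv$temps, horizon = horizon)
    total <- total + survey_sse(tr, sv, stage_set, adult_weight)
  }
  total
}

survey_sse <- function(tr, sv, stage_set, adult_weight) {
  total <- 0
  for (s in intersect(stage_set, unique(sv$obs$stage))) {
    o <- sv$obs[sv$obs$stage == s, , drop = FALSE]
    pred <- cumulative_emergence_at(tr, s, o$date)
    total <- total + sum((o$cumulative_percent - pred)^2)
  }
  if (adult_weight > 0 && !is.na(sv$first_adult_day)) {
    d1 <- emergence_quantile_day(tr, "adult", 1)
    if (is.na(d1)) d1 <- max(tr$day) + 7   # no simulated adults: late onset
    total <- total + adult_weight * (d1 - sv$first_adult_day)^2
  }
  total
}

#' Refine the stage rate functions against field surveys
#'
#' Step (i) of the field calibration: starting from chamber-derived rate
#' functions, minimizes the summed squared differences between observed
#' and simulated cumulative emergence curves of the five nymphal instars
#' across all surveys, with the first-adult onset entering as a
#' half-weighted penalty on the simulated 1%-adult date. The initial age
#' distribution and a provisional diapause rule are held fixed. Descent is
#' blockwise Nelder-Mead over the six Briere triples (`sweeps` passes);
#' the refined objective never exceeds the starting one.
#'
#' @param surveys A list of `"spuma_survey"` objects (each >= 5 dates).
#' @param start A [stage_param_set()]: the starting rates.
#' @param age_dist An [age_distribution()], held fixed.
#' @param diapause A provisional [diapause_params()] pair.
#' @param sweeps Blockwise passes over the stages (default 2).
#' @param maxit_block Nelder-Mead cap per block (default 150).
#' @param adult_weight Weight of the first-adult onset term (default 0.5).
#' @param grid_cells Age cells used in the embedded simulations.
#' @return An object of class `"spuma_rate_fit"`: `stages`, `objective`
#'   (`initial`, `final`), `trace`.
#' @export
calibrate_rates <- function(surveys, start, age_dist, diapause,
                            sweeps = 2, maxit_block = 150,
                            adult_weight = 0.5, grid_cells = 100L) {
  surveys <- survey_check(surveys)
  stopifnot(inherits(start, "stage_params"), inherits(age_dist, "age_dist"),
            inherits(diapause, "diapause_params"))
  ndates <- vapply(surveys, function(s) length(unique(s$obs$date)),
                   integer(1))
  if (any(ndates < 5L)) stop("each survey needs at least 5 sampling dates")

  cur <- start
  obj <- function(st) survey_objective(surveys, st, age_dist, diapause,
                                       adult_weight = adult_weight,
                                       grid_cells = grid_cells)
  f0 <- obj(cur)
  trace <- c(initial = f0)
  best <- f0
  mk <- function(v) briere_params(min(v[2], v[3] - 1), v[3], v_max = v[1])
  pen3 <- function(v)
    penalized(v[1], param_bounds$v_max[1], param_bounds$v_max[2]) +
    penalized(v[2], param_bounds$t_inf[1], param_bounds$t_inf[2]) +
    penalized(v[3], param_bounds$t_sup[1], param_bounds$t_sup[2])
  for (sw in seq_len(sweeps)) {
    for (j in 1:6) {
      fnJ <- function(p) {
        pen <- pen3(p)
        if (pen > 0) return(pen)
        st <- cur; st[[j]] <- mk(p)
        obj(st)
      }
      pj <- cur[[j]]
      o <- nm(c(briere_max_rate(pj), pj$t_inf, pj$t_sup), fnJ, maxit_block)
      if (o$value < best) {
        cur[[j]] <- mk(o$par)
        best <- o$value
      }
      trace <- c(trace, stats::setNames(best, paste0("s", sw, ".",
                                                     names(cur)[j])))
    }
  }
  structure(list(stages = cur, objective = c(initial = f0, final = best),
                 trace = trace),
            class = "spuma_rate_fit")
}

#' @export
print.spuma_rate_fit <- function(x, ...) {
  cat(sprintf("Field rate calibration: objective %.4g -> %.4g (%.0f%% reduction)\n",
              x$objective["initial"], x$objective["final"],
              100 * (1 - x$objective["final"] / x$objective["initial"])))
  print(x$stages)
  invisible(x)
}

#' @export
coef.spuma_rate_fit <- function(object, ...) {
  unlist(lapply(object$stages, function(p)
    c(t_inf = p$t_inf, t_sup = p$t_sup, v_max = briere_max_rate(p))))
}

#' Candidate grid for the diapause parameters
#'
#' The tested ranges are 3.0-10.0 degC for the threshold temperature and
#' 30-130 DD for the cumulative requirement; step sizes are configurable
#' but the candidates must stay within those ranges.
#'
#' @param t_e Threshold candidates (deg C), default `seq(3, 10, by = 0.5)`.
#' @param dd_e Degree-day candidates, default `seq(30, 130, by = 10)`.
#' @return An object of class `"diapause_grid"`.
#' @export
diapause_grid <- function(t_e = seq(3, 10, by = 0.5),
                          dd_e = seq(30, 130, by = 10)) {
  if (any(t_e < 3 - 1e-9) || any(t_e > 10 + 1e-9))
    stop("'t_e' candidates must lie within 3.0-10.0 degC")
  if (any(dd_e < 30 - 1e-9) || any(dd_e > 130 + 1e-9))
    stop("'dd_e' candidates must lie within 30-130 DD")
  structure(list(t_e = sort(unique(t_e)), dd_e = sort(unique(dd_e))),
            class = "diapause_grid")
}

#' Grid search for the diapause termination parameters
#'
#' Step (ii) of the field calibration: with the rate functions fixed,
#' every `(t_e, dd_e)` pair of the grid is evaluated exhaustively. The
#' objective is the summed squared difference between observed and
#' simulated cumulative emergence restricted to the 3rd, 4th and 5th
#' nymphal instars (the early-instar field curves being the least
#' reliable). A pair whose diapause never terminates within a survey's
#' series is scored against that survey's curves with zero simulated
#' emergence (a natural penalty), never an exception. Ties are broken
#' deterministically: smallest objective, then smallest `dd_e`, then
#' smallest `t_e`.
#'
#' Since `(t_e, dd_e)` influences the dynamics only through the
#' termination day, simulations are shared between all grid pairs that
#' terminate on the same day — the exhaustive search costs tens, not
#' hundreds, of forward runs per survey.
#'
#' @param surveys List of `"spuma_survey"` objects.
#' @param stages A [stage_param_set()] (fixed, from step (i)).
#' @param age_dist An [age_distribution()] (fixed).
#' @param grid A [diapause_grid()].
#' @param grid_cells Age cells used in the embedded simulations.
#' @return An object of class `"spuma_diapause_fit"`: `diapause` (the
#'   arg-min [diapause_params()]), `objective`, and `surface` (data frame
#'   `t_e`, `dd_e`, `objective` over the whole grid).
#' @export
calibrate_diapause <- function(surveys, stages, age_dist,
                               grid = diapause_grid(), grid_cells = 100L) {
  surveys <- survey_check(surveys)
  stopifnot(inherits(stages, "stage_params"), inherits(age_dist, "age_dist"),
            inherits(grid, "diapause_grid"))
  pairs <- expand.grid(t_e = grid$t_e, dd_e = grid$dd_e,
                       KEEP.OUT.ATTRS = FALSE)
  surf <- numeric(nrow(pairs))
  late <- stage_names[4:6]                        # N3, N4, N5

  for (sv in surveys) {
    horizon <- last_covered_day(sv$temps)
    # termination day for every pair: cumulative DD curves per threshold
    term <- integer(nrow(pairs))
    for (te in grid$t_e) {
      dd <- degree_days(sv$temps, te)
      idx <- which(pairs$t_e == te)
      for (i in idx) {
        hit <- which(dd$cum_dd >= pairs$dd_e[i])
        term[i] <- if (length(hit)) dd$day[hit[1L]] else NA_integer_
      }
    }
    # one simulation per distinct termination day
    m <- phenology_model(stages, diapause_params(0, 0), age_dist,
                         grid_cells = grid_cells)
    udays <- unique(term[!is.na(term) & term <= horizon])
    sse_by_day <- stats::setNames(vapply(udays, function(d) {
      tr <- simulate(m, temps = sv$temps, horizon = horizon,
                     bypass_diapause = TRUE, start_day = d)
      survey_sse(tr, sv, late, adult_weight = 0)
    }, numeric(1)), udays)
    zero_sse <- sum(sv$obs$cumulative_percent[sv$obs$stage %in% late]^2)
    surf <- surf + ifelse(is.na(term) | term > horizon, zero_sse,
                          sse_by_day[as.character(term)])
  }

  ord <- order(surf, pairs$dd_e, pairs$t_e)
  best <- ord[1L]
  structure(list(diapause = diapause_params(pairs$t_e[best],
                                            pairs$dd_e[best]),
                 objective = surf[best],
                 surface = data.frame(t_e = pairs$t_e, dd_e = pairs$dd_e,
                                      objective = surf)),
            class = "spuma_diapause_fit")
}

#' @export
print.spuma_diapause_fit <- function(x, ...) {
  cat(sprintf("Diapause grid search: Te = %g degC, DDe = %g DD (objective %.4g over %d pairs)\n",
              x$diapause$t_e, x$diapause$dd_e, x$objective,
              nrow(x$surface)))
  invisible(x)
}

#' @export
coef.spuma_diapause_fit <- function(object, ...) {
  c(t_e = object$diapause$t_e, dd_e = object$diapause$dd_e)
}

#' @export
plot.spuma_diapause_fit <- function(x, ...) {
  te <- sort(unique(x$surface$t_e))
  dd <- sort(unique(x$surface$dd_e))
  z <- matrix(x$surface$objective[order(x$surface$dd_e, x$surface$t_e)],
              nrow = length(te))
  graphics::image(te, dd, z, xlab = "Te (degC)", ylab = "DDe (degree-days)",
                  main = "Diapause calibration objective", ...)
  graphics::points(x$diapause$t_e, x$diapause$dd_e, pch = 4, cex = 2,
                   lwd = 3)
  invisible(x)
}
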