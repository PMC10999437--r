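#' Initial distribution of egg physiological age
#'
#' On 1 January the overwintering eggs are at various points of their
#' embryonic development; the spread is described by a Beta distribution
#' over physiological age \eqn{x \in [0, 1]}. The estimate for Italian
#' populations is Beta(5.67, 1.05), i.e. 90% of eggs between ages 0.58
#' and 0.99.
#'
#' @param alpha,beta Beta shape parameters (> 0).
#' @return An object of class `"age_dist"`.
#' @export
age_distribution <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            length(alpha) == 1L, length(beta) == 1L)
  if (alpha <= 0 || beta <= 0) stop("Beta shapes must be positive")
  structure(list(alpha = alpha, beta = beta), class = "age_dist")
}

#' @export
print.age_dist <- function(x, ...) {
  q <- stats::qbeta(c(0.05, 0.95), x$alpha, x$beta)
  cat(sprintf("Initial egg age ~ Beta(%.2f, %.2f); central 90%% in [%.2f, %.2f]\n",
              x$alpha, x$beta, q[1], q[2]))
  invisible(x)
}

#' Phenology model object
#'
#' Bundles everything the forward simulator needs: the six stage rate
#' functions, the diapause rule, the initial egg-age distribution, the
#' initial cohort size and the numerical settings of the age-structured
#' (Kolmogorov) solver.
#'
#' @param stages A [stage_param_set()].
#' @param diapause A [diapause_params()] object.
#' @param age_dist An [age_distribution()] object.
#' @param n_eggs Initial number of diapausing eggs on 1 January
#'   (default 100).
#' @param grid_cells Number of uniform cells of the age grid on `[0, 1]`
#'   (default 200, minimum 50).
#' @param cfl Courant safety factor in `(0, 1]` used to pick the substep
#'   (default 1).
#' @param diffusivity Optional constant diffusivity along age
#'   (age^2/day, default 0 = pure advection). Experimental; kept for
#'   sensitivity analyses.
#' @return An object of class `"spuma_model"`.
#' @seealso [spuma_preset()], [simulate.spuma_model()]
#' @export
phenology_model <- function(stages, diapause, age_dist, n_eggs = 100,
                            grid_cells = 200L, cfl = 1, diffusivity = 0) {
  stopifnot(inherits(stages, "stage_params"),
            inherits(diapause, "diapause_params"),
            inherits(age_dist, "age_dist"))
  grid_cells <- as.integer(grid_cells)
  if (grid_cells < 50L) stop("'grid_cells' must be at least 50")
  if (cfl <= 0 || cfl > 1) stop("'cfl' must be in (0, 1]")
  if (n_eggs <= 0) stop("'n_eggs' must be positive")
  if (diffusivity < 0) stop("'diffusivity' must be non-negative")
  structure(list(stages = stages, diapause = diapause, age_dist = age_dist,
                 n_eggs = n_eggs, grid_cells = grid_cells, cfl = cfl,
                 diffusivity = diffusivity),
            class = "spuma_model")
}

#' @export
print.spuma_model <- function(x, ...) {
  cat("Spittlebug phenology model\n")
  print(x$stages)
  print(x$diapause)
  print(x$age_dist)
  cat(sprintf("  %g initial eggs; %d age cells, CFL %.2f, diffusivity %g\n",
              x$n_eggs, x$grid_cells, x$cfl, x$diffusivity))
  invisible(x)
}

#' @export
summary.spuma_model <- function(object, ...) print(object, ...)

#' @export
coef.spuma_model <- function(object, ...) {
  out <- unlist(lapply(object$stages, function(p)
    c(t_inf = p$t_inf, t_sup = p$t_sup, v_max = briere_max_rate(p))))
  c(out, t_e = object$diapause$t_e, dd_e = object$diapause$dd_e,
    alpha = object$age_dist$alpha, beta = object$age_dist$beta)
}

#' Initialize the population state
#'
#' Places `n_eggs` individuals in the egg stage, distributed over the age
#' grid according to the Beta density evaluated at cell midpoints and
#' renormalized so the discrete total is exactly `n_eggs`; all other
#' stages start empty.
#'
#' @param n_eggs Initial cohort size (default 100).
#' @param age_dist An [age_distribution()].
#' @param grid_cells Number of age cells (>= 50).
#' @return An object of class `"spuma_state"` with fields `mass`
#'   (`grid_cells` x 6 matrix of cell masses), `phase`, `adult_emerged`,
#'   `cum_entries` (entries into stages 2..7) and `clock` (days).
#' @export
initialize_population <- function(n_eggs = 100, age_dist, grid_cells = 200L) {
  stopifnot(inherits(age_dist, "age_dist"))
  grid_cells <- as.integer(grid_cells)
  if (grid_cells < 50L) stop("'grid_cells' must be at least 50")
  dx <- 1 / grid_cells
  mids <- (seq_len(grid_cells) - 0.5) * dx
  dens <- stats::dbeta(mids, age_dist$alpha, age_dist$beta)
  if (!all(is.finite(dens)) || sum(dens) <= 0)
    stop("Beta density is degenerate on this grid")
  mass <- matrix(0, grid_cells, 6L,
                 dimnames = list(NULL, names_developing()))
  mass[, 1L] <- n_eggs * dens / sum(dens)
  structure(list(mass = mass, phase = numeric(6L), adult_emerged = 0,
                 cum_entries = stats::setNames(numeric(6L), stage_names[2:7]),
                 clock = 0, grid_cells = grid_cells),
            class = "spuma_state")
}

names_developing <- function() stage_names[1:6]

#' @export
print.spuma_state <- function(x, ...) {
  tot <- colSums(x$mass)
  cat(sprintf("Population state at t = %.2f d (grid %d):\n", x$clock,
              x$grid_cells))
  print(round(c(tot, adult = x$adult_emerged), 3))
  invisible(x)
}

# Total individuals currently tracked (all stages + emerged adults).
total_mass <- function(state) sum(state$mass) + state$adult_emerged

#' Advance the population by one time step
#'
#' One step of the conservative upwind transport at temperature `temp`:
#' every stage's density moves along age at its Briere velocity, mass
#' crossing `x = 1` enters the next stage at `x = 0` within the same step,
#' and outflow from N5 accumulates as emerged adults. The step must
#' respect the stability constraint `max_i v_i(temp) * dt <= dx`.
#'
#' @param state A `"spuma_state"` object.
#' @param temp Air temperature (deg C) during the step.
#' @param dt Step length (days).
#' @param params A [stage_param_set()].
#' @param diffusivity Optional constant diffusivity (default 0).
#' @return The updated `"spuma_state"`.
#' @export
step_population <- function(state, temp, dt, params, diffusivity = 0) {
  stopifnot(inherits(state, "spuma_state"), inherits(params, "stage_params"))
  dx <- 1 / state$grid_cells
  v <- vapply(params, function(p) briere_rate(temp, p), numeric(1))
  vmax <- max(v)
  if (vmax * dt > dx + 1e-12)
    stop(sprintf("dt = %g violates the stability constraint; maximal admissible dt is %g days",
                 dt, dx / vmax))
  dc <- diffusivity * dt / dx^2
  if (dc > 0.5) stop("diffusive stability violated; reduce dt or diffusivity")
  res <- advect_run(state$mass, state$phase, state$adult_emerged,
                    as.numeric(state$cum_entries),
                    matrix(v * dt / dx, nrow = 1L),
                    integer(0), dc)
  state$mass <- res$mass
  dimnames(state$mass) <- list(NULL, names_developing())
  state$phase <- res$phase
  state$adult_emerged <- res$adult
  state$cum_entries <- stats::setNames(res$cum_in, stage_names[2:7])
  state$clock <- state$clock + dt
  state
}

#' Simulate the seasonal phenology
#'
#' Runs the full forward model: eggs are held in diapause until the
#' degree-day requirement is met (see [diapause_termination_day()]), then
#' the age-structured transport is integrated under the supplied
#' temperature forcing, with cumulative entries into each stage recorded
#' daily. The model is deterministic, so `nsim`/`seed` are accepted for
#' compatibility with the generic but ignored.
#'
#' @param object A [phenology_model()] (or [spuma_preset()]) object.
#' @param nsim,seed Ignored (deterministic model).
#' @param temps A [temperature_series()] covering the simulated window.
#' @param horizon Last Julian day to simulate (default: last day covered
#'   by `temps`).
#' @param bypass_diapause If `TRUE`, skip the diapause phase and start
#'   development immediately at `start_day` (used for climatic-chamber
#'   cohorts, which are post-storage).
#' @param start_day First simulated day (default 1).
#' @param ... Unused.
#' @return An object of class `"spuma_traj"`: daily cumulative entries
#'   (counts and % of the initial cohort) into stages N1..N5 and adult,
#'   the diapause termination day, and the final solver state. If diapause
#'   never terminates within the series, an all-zero trajectory is
#'   returned with a warning.
#' @examples
#' m <- spuma_preset("calibrated", grid_cells = 100)
#' w <- weather_spec(seed = 1)
#' ts <- generate_temperature_series(w, days = 160)
#' tr <- simulate(m, temps = ts)
#' tr
#' @export
simulate.spuma_model <- function(object, nsim = 1, seed = NULL, temps,
                                 horizon = NULL, bypass_diapause = FALSE,
                                 start_day = 1L, ...) {
  stopifnot(inherits(temps, "spuma_temps"))
  if (is.null(horizon)) horizon <- last_covered_day(temps)
  horizon <- as.integer(horizon)
  if (horizon > last_covered_day(temps))
    stop("temperature series ends before the requested horizon (day ",
         horizon, ")")

  if (bypass_diapause) {
    t_start <- as.integer(start_day)
  } else {
    t_start <- diapause_termination_day(temps, object$diapause,
                                        start = start_day)
    if (is.na(t_start) || t_start > horizon) {
      if (is.na(t_start))
        warning("diapause requirement never met within the series; empty trajectory")
      t_start <- NA_integer_
    }
  }

  state <- initialize_population(object$n_eggs, object$age_dist,
                                 object$grid_cells)
  days <- seq.int(min(1L, start_day), horizon)   # record from Jan 1
  counts <- matrix(0, length(days), 6L,
                   dimnames = list(NULL, stage_names[2:7]))

  if (!is.na(t_start)) {
    n_days <- horizon - t_start + 1L
    dx <- 1 / object$grid_cells
    vmax <- max(vapply(object$stages, briere_max_rate, numeric(1)))
    n_sub <- max(1L, as.integer(ceiling(vmax / (object$cfl * dx))))
    dt <- 1 / n_sub
    n_steps <- n_days * n_sub
    # development begins on the termination day, i.e. at time t_start - 1
    tmid <- (t_start - 1) + (seq_len(n_steps) - 0.5) * dt
    tk <- temp_at(temps, tmid)
    courant <- vapply(object$stages,
                      function(p) briere_rate(tk, p) * dt / dx,
                      numeric(n_steps))
    dc <- object$diffusivity * dt / dx^2
    if (dc > 0.5) stop("diffusive stability violated; increase grid_cells or lower diffusivity")
    res <- advect_run(state$mass, state$phase, state$adult_emerged,
                      as.numeric(state$cum_entries), courant,
                      seq_len(n_days) * n_sub, dc)
    state$mass <- res$mass
    dimnames(state$mass) <- list(NULL, names_developing())
    state$phase <- res$phase
    state$adult_emerged <- res$adult
    state$cum_entries <- stats::setNames(res$cum_in, stage_names[2:7])
    state$clock <- horizon
    counts[match(seq.int(t_start, horizon), days), ] <- res$rec
  }

  structure(list(day = days, counts = counts,
                 percent = counts / object$n_eggs * 100,
                 n_init = object$n_eggs, termination_day = t_start,
                 final_state = state, model = object),
            class = "spuma_traj")
}

#' @export
print.spuma_traj <- function(x, ...) {
  cat(sprintf("Phenology trajectory, days %d-%d; diapause termination day: %s\n",
              x$day[1L], x$day[length(x$day)],
              ifelse(is.na(x$termination_day), "not reached",
                     x$termination_day)))
  cat("Final cumulative emergence (% of initial eggs):\n")
  print(round(x$percent[nrow(x$percent), ], 1))
  invisible(x)
}

#' @export
summary.spuma_traj <- function(object, ...) {
  qs <- c(1, 50, 95)
  tab <- sapply(stage_names[2:7], function(s)
    sapply(qs, function(q) emergence_quantile_day(object, s, q)))
  rownames(tab) <- paste0(qs, "%")
  cat("Emergence dates (Julian day at 1/50/95% cumulative emergence):\n")
  print(round(tab, 1))
  invisible(tab)
}

#' @export
plot.spuma_traj <- function(x, stages = stage_names[2:7], ...) {
  cols <- match(stages, colnames(x$percent))
  graphics::matplot(x$day, x$percent[, cols, drop = FALSE], type = "l",
                    lty = 1, lwd = 2, xlab = "Julian day",
                    ylab = "Cumulative emergence (%)", ylim = c(0, 100), ...)
  graphics::legend("topleft", legend = stages, col = seq_along(cols),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.spuma_traj <- function(x, ...) {
  data.frame(julian_day = rep(x$day, 6L),
             stage = rep(colnames(x$counts), each = length(x$day)),
             cumulative_count = as.vector(x$counts),
             cumulative_percent = as.vector(x$percent))
}

#' Cumulative emergence at given dates
#'
#' Linear interpolation of a trajectory's normalized cumulative emergence
#' curve for one stage. "Emergence" into the egg stage is undefined (eggs
#' enter the system as the initial condition), so stage 1 is rejected.
#'
#' @param traj A `"spuma_traj"` object.
#' @param stage Stage index 2..7 or name (`"N1"`..`"N5"`, `"adult"`).
#' @param dates Julian days within the trajectory range.
#' @return Percentages in `[0, 100]`, non-decreasing with date.
#' @export
cumulative_emergence_at <- function(traj, stage, dates) {
  stopifnot(inherits(traj, "spuma_traj"))
  i <- match_stage(stage)
  if (i == 1L) stop("eggs enter the system; they do not emerge (stage 1)")
  rng <- range(traj$day)
  if (any(dates < rng[1L] - 1e-9 | dates > rng[2L] + 1e-9))
    stop("dates outside the trajectory horizon [", rng[1L], ", ", rng[2L], "]")
  stats::approx(traj$day, traj$percent[, i - 1L], xout = dates,
                rule = 2)$y
}

# Julian day at which a stage's cumulative emergence first reaches q (%).
# Returns NA if never reached.
emergence_quantile_day <- function(traj, stage, q) {
  i <- match_stage(stage)
  y <- traj$percent[, i - 1L]
  if (max(y) < q) return(NA_real_)
  k <- which(y >= q)[1L]
  if (k == 1L || y[k] == y[k - 1L]) return(traj$day[k])
  traj$day[k - 1L] + (q - y[k - 1L]) / (y[k] - y[k - 1L])
}

#' Predict cumulative emergence under new forcing
#'
#' Convenience wrapper: simulates the model under `temps` and reads the
#' cumulative emergence of one stage at the requested dates.
#'
#' @param object A [phenology_model()] object.
#' @param temps A [temperature_series()].
#' @param dates Julian days.
#' @param stage Stage index 2..7 or name.
#' @param ... Passed to [simulate.spuma_model()].
#' @return Percentages at `dates`.
#' @export
predict.spuma_model <- function(object, temps, dates, stage = "N3", ...) {
  tr <- simulate(object, temps = temps,
                 horizon = max(ceiling(dates)), ...)
  cumulative_emergence_at(tr, stage, dates)
}
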