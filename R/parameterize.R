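# Estimation of the stage rate functions and the initial egg-age Beta
# distribution from constant-temperature chamber cohort data.

# Pool a chamber dataset into per-temperature observed cumulative
# emergence curves (%). `cohort` is the per-replicate cohort size; when
# NULL it is taken from the dataset attribute or, failing that, inferred
# as the per-replicate maximum cumulative count (valid when at least egg
# hatch runs to completion within the observation horizon).
chamber_observed <- function(chamber, cohort = NULL) {
  stopifnot(is.data.frame(chamber))
  need <- c("temperature_C", "replicate", "day", "stage", "cumulative_count")
  miss <- setdiff(need, names(chamber))
  if (length(miss))
    stop("chamber data lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(chamber)) stop("chamber dataset is empty")
  if (is.null(cohort)) cohort <- attr(chamber, "cohort")
  lapply(split(chamber, chamber$temperature_C), function(d) {
    reps <- unique(d$replicate)
    coh <- cohort
    if (is.null(coh))
      coh <- mean(vapply(split(d$cumulative_count, d$replicate), max,
                         numeric(1)))
    days <- sort(unique(d$day))
    pct <- sapply(stage_names[2:7], function(s) {
      ds <- d[d$stage == s, , drop = FALSE]
      if (!nrow(ds)) return(rep(NA_real_, length(days)))
      tot <- tapply(ds$cumulative_count, ds$day, sum)
      100 * as.numeric(tot[match(days, as.numeric(names(tot)))]) /
        (coh * length(reps))
    })
    list(temperature = d$temperature_C[1L], days = days,
         pct = matrix(pct, nrow = length(days),
                      dimnames = list(NULL, stage_names[2:7])))
  })
}

#' Fit a Gamma distribution to a stage emergence curve
#'
#' Approximates the pooled cumulative emergence curve of one stage at one
#' chamber temperature with a Gamma CDF (least squares on the normalized
#' curve), the classical smoothing used to summarise cohort emergence.
#' The fit is a descriptive layer: the development-rate estimation itself
#' targets the raw censored curves.
#'
#' @param chamber A chamber dataset (see
#'   [generate_chamber_experiment()] / [read_chamber_csv()]).
#' @param stage Stage reached, index 2..7 or name (`"N1"`..`"adult"`).
#' @param temperature Chamber temperature to use (required when the
#'   dataset holds several).
#' @param cohort Per-replicate cohort size (see Details of
#'   [fit_development_params()]).
#' @return An object of class `"spuma_gamma"` with fields `shape`, `scale`
#'   (days), `stage`, `temperature`, `days`, `observed` (fractions) and
#'   `fitted`.
#' @export
fit_gamma_emergence <- function(chamber, stage, temperature = NULL,
                                cohort = NULL) {
  obs <- chamber_observed(chamber, cohort)
  if (is.null(temperature)) {
    if (length(obs) > 1L)
      stop("dataset holds several temperatures; supply 'temperature'")
    temperature <- obs[[1L]]$temperature
  }
  o <- obs[[as.character(temperature)]]
  if (is.null(o)) stop("no data at temperature ", temperature)
  s <- match_stage(stage)
  if (s < 2L) stop("stage must be 2..7")
  frac <- o$pct[, s - 1L] / 100
  keep <- !is.na(frac)
  days <- o$days[keep]; frac <- frac[keep]
  fin <- max(frac)
  if (fin <= 0) stop("no emergence observed for this stage/temperature")
  fr <- frac / fin
  inc <- diff(c(0, fr))
  if (sum(inc > 1e-9) < 3L)
    warning("emergence concentrated in fewer than 3 observation intervals; near-point Gamma fit")
  mu <- sum(days * inc) / sum(inc)
  v <- max(sum(days^2 * inc) / sum(inc) - mu^2, (mu * 0.02)^2)
  start <- c(log(mu^2 / v), log(v / mu))
  fn <- function(p) sum((stats::pgamma(days, exp(p[1]), scale = exp(p[2])) -
                           fr)^2)
  opt <- stats::optim(start, fn, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  structure(list(shape = exp(opt$par[1]), scale = exp(opt$par[2]),
                 stage = stage_names[s], temperature = temperature,
                 days = days, observed = fr,
                 fitted = stats::pgamma(days, exp(opt$par[1]),
                                        scale = exp(opt$par[2])),
                 sse = opt$value),
            class = "spuma_gamma")
}

#' @export
print.spuma_gamma <- function(x, ...) {
  cat(sprintf("Gamma emergence fit (%s at %g degC): shape %.3f, scale %.3f d (mean %.1f d, SSE %.2e)\n",
              x$stage, x$temperature, x$shape, x$scale, x$shape * x$scale,
              x$sse))
  invisible(x)
}

#' @export
plot.spuma_gamma <- function(x, ...) {
  tt <- seq(0, max(x$days), length.out = 200)
  graphics::plot(x$days, x$observed, pch = 8, xlab = "Day",
                 ylab = "Cumulative emergence (fraction)", ylim = c(0, 1),
                 ...)
  graphics::lines(tt, stats::pgamma(tt, x$shape, scale = x$scale), lwd = 2)
  invisible(x)
}

# ---- development-parameter estimation -------------------------------------

param_bounds <- list(t_inf = c(0, 15), t_sup = c(25, 40),
                     v_max = c(1e-4, 1), shape = c(0.05, 50))

penalized <- function(p, lo, hi) {
  excess <- pmax(lo - p, 0) + pmax(p - hi, 0)
  if (any(excess > 0)) 1e8 * (1 + sum(excess^2)) else 0
}

# Predicted curves for one chamber temperature under the chosen engine.
chamber_predicted <- function(stages, age_dist, temperature, days, stage_idx,
                              engine, grid_cells = 100L) {
  if (engine == "characteristics") {
    characteristics_curve(stages, age_dist, temperature, stage_idx, days)
  } else {
    ts <- temperature_series(rep(temperature, max(days) + 1L),
                             cadence = "daily")
    m <- phenology_model(stages, diapause_params(0, 0), age_dist,
                         grid_cells = grid_cells)
    tr <- simulate(m, temps = ts, bypass_diapause = TRUE)
    cumulative_emergence_at(tr, stage_idx, days)
  }
}

chamber_objective <- function(stages, age_dist, obs, engine,
                              stage_set = 2:7, grid_cells = 100L) {
  total <- 0
  for (o in obs) {
    for (s in stage_set) {
      y <- o$pct[, s - 1L]
      if (all(is.na(y))) next
      pred <- chamber_predicted(stages, age_dist, o$temperature, o$days, s,
                                engine, grid_cells)
      total <- total + sum((y - pred)^2, na.rm = TRUE)
    }
  }
  total
}

nm <- function(par, fn, maxit = 400) {
  stats::optim(par, fn, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
}

#' Estimate development parameters from chamber cohorts
#'
#' Fits the full stage-structured model to constant-temperature cohort
#' data (the four-chamber design at 10/18/24/30 degC) by least squares on
#' the observed cumulative emergence curves, jointly estimating the six
#' Briere triples and the initial Beta age distribution. The diapause
#' phase is bypassed: chamber eggs are post-storage.
#'
#' The minimization mirrors the iterative constrained procedure used for
#' this model class: the objective at the initial guess is evaluated
#' first and, if already below the objective-change tolerance (0.1), the
#' guess is returned unchanged; otherwise blockwise Nelder-Mead descent
#' (egg + Beta block on the hatch curves, then one block per instar on
#' its entry curves) is followed by an optional joint refinement pass.
#' Step tolerance 1e-6 and objective-change tolerance 0.1 are the
#' stopping rules. The final objective never exceeds the initial one.
#'
#' Engines: `"characteristics"` (default) evaluates the model's exact
#' constant-temperature solution, which is both fast and free of grid
#' error; `"pde"` runs the gridded solver instead (useful to confirm grid
#' adequacy).
#'
#' @param chamber Chamber dataset: data frame with columns
#'   `temperature_C`, `replicate`, `day`, `stage`, `cumulative_count`.
#' @param init A list with elements `stages` (a [stage_param_set()]) and
#'   `age_dist` (an [age_distribution()]): the starting point.
#' @param cohort Per-replicate cohort size; default taken from the
#'   dataset's `cohort` attribute or inferred from per-replicate maxima.
#' @param engine `"characteristics"` or `"pde"`.
#' @param refine Run the final joint refinement pass (default `TRUE`).
#' @param maxit_block,maxit_joint Nelder-Mead iteration caps.
#' @param fn_tol Objective-change stopping tolerance (default 0.1).
#' @param grid_cells Age cells for the `"pde"` engine.
#' @return An object of class `"spuma_param_fit"`: fields `stages`,
#'   `age_dist`, `objective` (`initial`, `final`), `trace`, `engine`,
#'   `converged`.
#' @export
fit_development_params <- function(chamber, init, cohort = NULL,
                                   engine = c("characteristics", "pde"),
                                   refine = TRUE, maxit_block = 400,
                                   maxit_joint = 600, fn_tol = 0.1,
                                   grid_cells = 100L) {
  engine <- match.arg(engine)
  stopifnot(is.list(init), inherits(init$stages, "stage_params"),
            inherits(init$age_dist, "age_dist"))
  obs <- chamber_observed(chamber, cohort)
  if (length(obs) < 1L) stop("no chamber temperatures found")

  cur_st <- init$stages
  cur_age <- init$age_dist
  f0 <- chamber_objective(cur_st, cur_age, obs, engine,
                          grid_cells = grid_cells)
  trace <- c(initial = f0)
  if (f0 <= fn_tol) {
    return(structure(list(stages = cur_st, age_dist = cur_age,
                          objective = c(initial = f0, final = f0),
                          trace = trace, engine = engine, converged = TRUE),
                     class = "spuma_param_fit"))
  }

  set_stage <- function(st, j, p) { st[[j]] <- p; st }
  mk_briere <- function(v) briere_params(min(v[2], v[3] - 1), v[3],
                                         v_max = v[1])
  pen3 <- function(v)
    penalized(v[1], param_bounds$v_max[1], param_bounds$v_max[2]) +
    penalized(v[2], param_bounds$t_inf[1], param_bounds$t_inf[2]) +
    penalized(v[3], param_bounds$t_sup[1], param_bounds$t_sup[2])

  # Block A: egg rate + Beta age on the hatch curves
  fnA <- function(p) {
    pen <- pen3(p[3:5]) +
      penalized(p[1], param_bounds$shape[1], param_bounds$shape[2]) +
      penalized(p[2], param_bounds$shape[1], param_bounds$shape[2])
    if (pen > 0) return(pen)
    st <- set_stage(cur_st, 1L, mk_briere(p[3:5]))
    chamber_objective(st, age_distribution(p[1], p[2]), obs, engine,
                      stage_set = 2L, grid_cells = grid_cells)
  }
  e <- cur_st[[1L]]
  startsA <- list(
    c(cur_age$alpha, cur_age$beta, briere_max_rate(e), e$t_inf, e$t_sup),
    c(2, 2, briere_max_rate(e), 3, 33),
    c(5, 1, 0.05, 6.5, 32))
  bestA <- NULL
  for (st0 in startsA) {
    o <- nm(st0, fnA, maxit_block)
    if (is.null(bestA) || o$value < bestA$value) bestA <- o
  }
  cur_age <- age_distribution(bestA$par[1], bestA$par[2])
  cur_st <- set_stage(cur_st, 1L, mk_briere(bestA$par[3:5]))
  trace <- c(trace, egg = bestA$value)

  # Instar blocks: stage j's velocity from the entries into stage j+1
  for (j in 2:6) {
    fnJ <- function(p) {
      pen <- pen3(p)
      if (pen > 0) return(pen)
      chamber_objective(set_stage(cur_st, j, mk_briere(p)), cur_age, obs,
                        engine, stage_set = j + 1L,
                        grid_cells = grid_cells)
    }
    pj <- cur_st[[j]]
    startsJ <- list(c(briere_max_rate(pj), pj$t_inf, pj$t_sup),
                    c(0.2, 3, 33), c(0.15, 5, 31))
    bestJ <- NULL
    for (st0 in startsJ) {
      o <- nm(st0, fnJ, maxit_block)
      if (is.null(bestJ) || o$value < bestJ$value) bestJ <- o
    }
    cur_st <- set_stage(cur_st, j, mk_briere(bestJ$par))
    trace <- c(trace, stats::setNames(bestJ$value, names(cur_st)[j]))
  }

  converged <- TRUE
  if (refine) {
    pack <- function(st, ad)
      c(ad$alpha, ad$beta,
        unlist(lapply(st, function(p) c(briere_max_rate(p), p$t_inf,
                                        p$t_sup)), use.names = FALSE))
    unpack <- function(p) {
      st <- cur_st
      for (j in 1:6) st[[j]] <- mk_briere(p[3 * j + 0:2])
      list(stages = st, age_dist = age_distribution(p[1], p[2]))
    }
    fnFull <- function(p) {
      pen <- penalized(p[1], param_bounds$shape[1], param_bounds$shape[2]) +
        penalized(p[2], param_bounds$shape[1], param_bounds$shape[2]) +
        sum(vapply(1:6, function(j) pen3(p[3 * j + 0:2]), numeric(1)))
      if (pen > 0) return(pen)
      u <- unpack(p)
      chamber_objective(u$stages, u$age_dist, obs, engine,
                        grid_cells = grid_cells)
    }
    oj <- stats::optim(pack(cur_st, cur_age), fnFull,
                       method = "Nelder-Mead",
                       control = list(maxit = maxit_joint, reltol = 1e-6))
    if (oj$value < min(utils::tail(trace, 1), f0)) {
      u <- unpack(oj$par)
      cur_st <- u$stages
      cur_age <- u$age_dist
    }
    converged <- oj$convergence == 0
    trace <- c(trace, joint = oj$value)
  }

  f1 <- chamber_objective(cur_st, cur_age, obs, engine,
                          grid_cells = grid_cells)
  if (f1 > f0) {            # never worse than the starting point
    cur_st <- init$stages; cur_age <- init$age_dist; f1 <- f0
  }
  structure(list(stages = cur_st, age_dist = cur_age,
                 objective = c(initial = f0, final = f1), trace = trace,
                 engine = engine, converged = converged),
            class = "spuma_param_fit")
}

#' @export
print.spuma_param_fit <- function(x, ...) {
  cat(sprintf("Chamber parameterization (%s engine): objective %.4g -> %.4g%s\n",
              x$engine, x$objective["initial"], x$objective["final"],
              if (isTRUE(x$converged)) "" else " (iteration cap reached)"))
  print(x$stages)
  print(x$age_dist)
  invisible(x)
}

#' @export
coef.spuma_param_fit <- function(object, ...) {
  c(unlist(lapply(object$stages, function(p)
    c(t_inf = p$t_inf, t_sup = p$t_sup, v_max = briere_max_rate(p)))),
    alpha = object$age_dist$alpha, beta = object$age_dist$beta)
}
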