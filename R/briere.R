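#' Briere temperature-development rate parameters
#'
#' Bundles the three constants of the Briere development-rate function
#' \eqn{v(T) = a\,T\,(T - T_{inf})\sqrt{T_{sup} - T}} used for every
#' preimaginal stage of the spittlebug: the empirical scale constant `a`,
#' the lower development threshold `t_inf` and the upper threshold `t_sup`
#' (both in degrees Celsius). Instead of `a`, the maximum rate `v_max`
#' (day^-1, attained at the optimum temperature) may be supplied; `a` is
#' then reconstructed with [scale_from_max()].
#'
#' @param t_inf Lower development threshold (deg C).
#' @param t_sup Upper development threshold (deg C); must exceed `t_inf`.
#' @param a Empirical scale constant (> 0). Exactly one of `a`, `v_max`.
#' @param v_max Maximum development rate (day^-1, > 0), alternative to `a`.
#' @return An object of class `"briere"` with fields `a`, `t_inf`, `t_sup`.
#' @examples
#' p <- briere_params(t_inf = 6.5, t_sup = 32, v_max = 0.0373)
#' briere_optimum(p)   # ~26.3 degC
#' @export
briere_params <- function(t_inf, t_sup, a = NULL, v_max = NULL) {
  stopifnot(is.numeric(t_inf), is.numeric(t_sup), length(t_inf) == 1L,
            length(t_sup) == 1L)
  if (t_inf >= t_sup)
    stop("'t_inf' (", t_inf, ") must be below 't_sup' (", t_sup, ")")
  if (is.null(a) == is.null(v_max))
    stop("supply exactly one of 'a' or 'v_max'")
  if (is.null(a)) a <- scale_from_max(v_max, t_inf, t_sup)
  if (!is.numeric(a) || length(a) != 1L || a <= 0)
    stop("'a' must be a single positive number")
  structure(list(a = a, t_inf = t_inf, t_sup = t_sup), class = "briere")
}

#' @export
print.briere <- function(x, ...) {
  cat(sprintf(
    "Briere rate: a = %.4g, thresholds [%.1f, %.1f] degC, max %.4f day^-1 at %.1f degC\n",
    x$a, x$t_inf, x$t_sup, briere_max_rate(x), briere_optimum(x)))
  invisible(x)
}

#' Briere development rate at a given temperature
#'
#' Evaluates \eqn{v(T) = a\,T\,(T - T_{inf})\sqrt{T_{sup} - T}} for
#' `t_inf <= T <= t_sup` and 0 outside that interval. The returned rate is
#' clamped below at zero: development cannot run backwards, even for the
#' (sub-zero) temperatures where the bare formula could go negative.
#'
#' @param temp Temperature(s), deg C. Vectorized.
#' @param params A [briere_params()] object.
#' @return Development rate(s), day^-1 (fraction of the stage completed per
#'   day).
#' @export
briere_rate <- function(temp, params) {
  stopifnot(inherits(params, "briere"))
  v <- numeric(length(temp))
  inside <- !is.na(temp) & temp >= params$t_inf & temp <= params$t_sup
  tt <- temp[inside]
  v[inside] <- params$a * tt * (tt - params$t_inf) * sqrt(params$t_sup - tt)
  v[is.na(temp)] <- NA_real_
  pmax(v, 0)
}

#' Optimum development temperature of a Briere function
#'
#' The unique interior maximizer of the Briere rate, from the closed-form
#' stationarity condition \eqn{5T^2 - (4 T_{sup} + 3 T_{inf}) T +
#' 2 T_{inf} T_{sup} = 0} (larger root). Computed analytically rather than
#' numerically so that the optimum is exact and independent of any grid.
#'
#' @param params A [briere_params()] object.
#' @return Optimum temperature (deg C), strictly inside `(t_inf, t_sup)`.
#' @export
briere_optimum <- function(params) {
  stopifnot(inherits(params, "briere"))
  b <- 4 * params$t_sup + 3 * params$t_inf
  c0 <- 2 * params$t_inf * params$t_sup
  (b + sqrt(b^2 - 20 * c0)) / 10
}

#' Maximum development rate of a Briere function
#'
#' @param params A [briere_params()] object.
#' @return Rate at the optimum temperature (day^-1).
#' @export
briere_max_rate <- function(params) {
  briere_rate(briere_optimum(params), params)
}

#' Reconstruct the Briere scale constant from a maximum rate
#'
#' The literature frequently reports the peak rate `v_max` and the two
#' thresholds rather than the raw scale constant `a`. This inverts the
#' relation: `a = v_max / (Topt (Topt - t_inf) sqrt(t_sup - Topt))` with
#' `Topt` the closed-form optimum.
#'
#' @param v_max Maximum development rate (day^-1, > 0).
#' @param t_inf,t_sup Lower/upper thresholds (deg C).
#' @return The scale constant `a` such that the resulting curve peaks at
#'   exactly `v_max`.
#' @export
scale_from_max <- function(v_max, t_inf, t_sup) {
  if (!is.numeric(v_max) || length(v_max) != 1L || v_max <= 0)
    stop("'v_max' must be a single positive number")
  if (t_inf >= t_sup) stop("'t_inf' must be below 't_sup'")
  b <- 4 * t_sup + 3 * t_inf
  topt <- (b + sqrt(b^2 - 40 * t_inf * t_sup)) / 10
  v_max / (topt * (topt - t_inf) * sqrt(t_sup - topt))
}

#' Per-stage Briere parameter set
#'
#' Ordered rate functions for the six developing stages: post-diapausing
#' egg and nymphal instars N1-N5. The adult stage carries no rate function
#' (only the flux of individuals out of N5 is modelled).
#'
#' @param egg,n1,n2,n3,n4,n5 [briere_params()] objects.
#' @return An object of class `"stage_params"`: a named list of six
#'   `"briere"` objects.
#' @export
stage_param_set <- function(egg, n1, n2, n3, n4, n5) {
  pars <- list(egg = egg, n1 = n1, n2 = n2, n3 = n3, n4 = n4, n5 = n5)
  ok <- vapply(pars, inherits, logical(1), what = "briere")
  if (!all(ok)) stop("all six stage parameters must be 'briere' objects")
  structure(pars, class = "stage_params")
}

#' @export
print.stage_params <- function(x, ...) {
  cat("Stage development-rate functions (Briere):\n")
  for (nm in names(x)) {
    p <- x[[nm]]
    cat(sprintf("  %-4s t_inf = %4.1f  t_sup = %4.1f  v_max = %.4f day^-1 (opt %.1f degC)\n",
                nm, p$t_inf, p$t_sup, briere_max_rate(p), briere_optimum(p)))
  }
  invisible(x)
}

#' Plot the stage rate functions
#'
#' Draws the six temperature-development rate curves on one panel.
#'
#' @param x A `"stage_params"` object.
#' @param from,to Temperature range (deg C).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.stage_params <- function(x, from = 0, to = 40, ...) {
  tt <- seq(from, to, by = 0.1)
  vv <- sapply(x, function(p) briere_rate(tt, p))
  graphics::matplot(tt, vv, type = "l", lty = 1, lwd = 2,
                    xlab = "Temperature (degC)",
                    ylab = "Development rate (1/day)", ...)
  graphics::legend("topleft", legend = names(x), col = seq_along(x),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

stage_names <- c("egg", "N1", "N2", "N3", "N4", "N5", "adult")

# Resolve a stage given as index 1..7 or name; returns the 1-based index.
match_stage <- function(stage) {
  if (is.numeric(stage)) {
    stage <- as.integer(stage)
    if (stage < 1L || stage > 7L) stop("stage index must be in 1..7")
    return(stage)
  }
  i <- match(tolower(stage), tolower(stage_names))
  if (is.na(i)) stop("unknown stage '", stage, "'")
  i
}
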