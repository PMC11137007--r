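#' Seasonal rate functions
#'
#' The model is driven by three per-day rates defined on the season
#' \eqn{[0, T]}: the photosynthetic rate per leaf area \eqn{p(t)} (carbon per
#' area per day), the heat-stress hazard \eqn{h(t)} (per day), and the
#' effectiveness of isoprene in suppressing that hazard \eqn{b(t)} (per unit
#' isoprene). Two parametric families are supported:
#'
#' * `rate_constant(level)` — time-invariant rate;
#' * `rate_exp_cosine(a1, b1, ...)` — an exponentially modulated cosine,
#'   \eqn{c \exp[a_1 + \sigma b_1 \cos(2\pi t/T)]} with \eqn{\sigma = \pm 1}.
#'   With `sign = -1` (the default) the rate peaks at midseason \eqn{t = T/2}
#'   at \eqn{c\,e^{a_1 + b_1}} and is lowest at the season boundaries; with
#'   `sign = +1` it instead dips at midseason. `b1` is the dimensionless
#'   shape factor: larger `b1` gives a sharper seasonal peak (or dip).
#'
#' Both families are strictly positive on the whole season, which the
#' hazard-suppression factor \eqn{1/(1 + b(t) s(t))} relies on.
#'
#' @param level Positive constant value of the rate.
#' @param a1 Dimensionless offset of the exponent.
#' @param b1 Dimensionless shape factor (>= 0).
#' @param scale Positive multiplier \eqn{c} in front of the exponential.
#' @param sign Either `-1` (midseason peak) or `+1` (midseason dip).
#' @param period Season length `T` (days) over which the rate is defined.
#' @return An object of class `iso_rate`.
#' @seealso [eval_rate()], [rate_set()]
#' @examples
#' h <- rate_exp_cosine(a1 = 0, b1 = 1)
#' eval_rate(h, 0.5)   # exp(1), the midsummer maximum
#' @export
rate_constant <- function(level, period = 1) {
  stopifnot(is.numeric(level), length(level) == 1L, is.finite(level))
  if (level <= 0) stop("constant rate 'level' must be strictly positive")
  check_period(period)
  structure(list(family = "constant", level = level, period = period),
            class = "iso_rate")
}

#' @rdname rate_constant
#' @export
rate_exp_cosine <- function(a1, b1, scale = 1, sign = -1, period = 1) {
  stopifnot(is.numeric(a1), is.numeric(b1), is.numeric(scale),
            length(a1) == 1L, length(b1) == 1L, length(scale) == 1L,
            is.finite(a1), is.finite(b1), is.finite(scale))
  if (b1 < 0) stop("shape factor 'b1' must be non-negative")
  if (scale <= 0) stop("'scale' must be strictly positive")
  if (!sign %in% c(-1, 1)) stop("'sign' must be -1 or +1")
  check_period(period)
  structure(list(family = "exp_cosine", a1 = a1, b1 = b1, scale = scale,
                 sign = sign, period = period),
            class = "iso_rate")
}

check_period <- function(period) {
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0) {
    stop("'period' (season length T) must be a positive finite scalar")
  }
  invisible(period)
}

#' @export
print.iso_rate <- function(x, ...) {
  if (x$family == "constant") {
    cat(sprintf("<iso_rate> constant, level = %g on [0, %g]\n",
                x$level, x$period))
  } else {
    cat(sprintf(
      "<iso_rate> %g * exp[%g %s %g cos(2*pi*t/%g)] on [0, %g]\n",
      x$scale, x$a1, if (x$sign < 0) "-" else "+", x$b1, x$period, x$period))
  }
  invisible(x)
}

#' Evaluate a rate function
#'
#' Evaluates an `iso_rate` at one or more times in the closed season
#' \eqn{[0, T]}. Evaluation is vectorised over `t`. Times outside the season
#' (beyond a tiny floating-point guard) are a domain error: the model is only
#' defined between leaf flush (`t = 0`) and leaf shedding (`t = T`).
#'
#' @param r An [rate_constant()] / [rate_exp_cosine()] object.
#' @param t Numeric vector of times (days).
#' @return Numeric vector of strictly positive rate values, same length as `t`.
#' @export
eval_rate <- function(r, t) {
  stopifnot(inherits(r, "iso_rate"), is.numeric(t))
  Tn <- r$period
  tol <- 1e-9 * max(Tn, 1)
  if (any(t < -tol | t > Tn + tol)) {
    stop(sprintf("time outside the season [0, %g]", Tn))
  }
  if (r$family == "constant") {
    rep(r$level, length(t))
  } else {
    r$scale * exp(r$a1 + r$sign * r$b1 * cos(2 * pi * t / Tn))
  }
}

#' Bundle of model rates
#'
#' Collects the three seasonal rates and the background leaf-loss rate `u`
#' into one object. All three rates must be defined on the same season
#' \eqn{[0, T]}. `u` (per day) is the hazard component that isoprene cannot
#' suppress; it enters the leaf dynamics additively.
#'
#' @param p Photosynthetic rate per leaf area, an `iso_rate`.
#' @param h Heat-stress hazard, an `iso_rate`.
#' @param b_eff Isoprene effectiveness, an `iso_rate`. Note this is the
#'   time-dependent effectiveness, distinct from the cosine shape factor `b1`
#'   of [rate_exp_cosine()].
#' @param u Non-negative scalar background loss rate (per day).
#' @return An object of class `iso_rateset`.
#' @export
rate_set <- function(p, h, b_eff, u = 0) {
  stopifnot(inherits(p, "iso_rate"), inherits(h, "iso_rate"),
            inherits(b_eff, "iso_rate"))
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u) || u < 0) {
    stop("background loss rate 'u' must be a non-negative finite scalar")
  }
  periods <- c(p$period, h$period, b_eff$period)
  if (diff(range(periods)) > 1e-12 * max(periods)) {
    stop("all rates must share the same season length T")
  }
  structure(list(p = p, h = h, b_eff = b_eff, u = u, period = p$period),
            class = "iso_rateset")
}

#' @export
print.iso_rateset <- function(x, ...) {
  cat("<iso_rateset> on [0,", x$period, "], u =", x$u, "\n")
  cat("  p:     "); print(x$p)
  cat("  h:     "); print(x$h)
  cat("  b_eff: "); print(x$b_eff)
  invisible(x)
}

#' Season-level parameters
#'
#' @param T Season length in days (the figures use `T = 1`, i.e. time is
#'   normalised to season fractions).
#' @param L0 Initial leaf area at flush (area units).
#' @param s_max Maximum isoprene production per leaf area per day, measured
#'   in carbon-cost units (same units as `p`). `s_max = 0` disables
#'   production entirely.
#' @param n_steps Grid resolution for the fixed-step integrators. The default
#'   20000 localises control-phase boundaries to about `5e-5 * T`.
#' @return An object of class `iso_season`.
#' @export
season_params <- function(T = 1, L0 = 1, s_max = 0.132, n_steps = 20000L) {
  check_period(T)
  stopifnot(is.numeric(L0), length(L0) == 1L, is.finite(L0),
            is.numeric(s_max), length(s_max) == 1L, is.finite(s_max))
  if (L0 <= 0) stop("'L0' must be strictly positive")
  if (s_max < 0) stop("'s_max' must be non-negative")
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 100L) stop("'n_steps' must be >= 100")
  structure(list(T = T, L0 = L0, s_max = s_max, n_steps = n_steps),
            class = "iso_season")
}

#' Leaf-area dynamics
#'
#' Right-hand side of the leaf-area ODE
#' \deqn{dL/dt = -\left(u + \frac{h(t)}{1 + b(t) s(t)}\right) L,}
#' where producing isoprene at rate `s` divides the hazard by
#' \eqn{1 + b(t)s}. Linear in `L`; vectorised over `t` (with `L`, `s`
#' recycled or matched).
#'
#' @param L Leaf area (>= 0).
#' @param t Time in `[0, T]`.
#' @param s Isoprene production rate per leaf area (>= 0).
#' @param rates An [rate_set()].
#' @return dL/dt, non-positive wherever `L >= 0`.
#' @export
leaf_rhs <- function(L, t, s, rates) {
  stopifnot(inherits(rates, "iso_rateset"))
  if (any(s < 0)) stop("production rate 's' must be non-negative")
  if (any(L < 0)) stop("leaf area 'L' must be non-negative")
  h <- eval_rate(rates$h, t)
  b <- eval_rate(rates$b_eff, t)
  -(rates$u + h / (1 + b * s)) * L
}

#' Objective integrand: instantaneous net photosynthesis
#'
#' The integrand of the season objective
#' \eqn{\phi = \int_0^T (p(t) - s(t)) L(t)\,dt}: carbon fixed per day minus
#' the carbon cost of isoprene production, per the current leaf area.
#'
#' @inheritParams leaf_rhs
#' @return Carbon flux `(p(t) - s) * L`.
#' @export
objective_integrand <- function(L, t, s, rates) {
  stopifnot(inherits(rates, "iso_rateset"))
  if (any(s < 0)) stop("production rate 's' must be non-negative")
  (eval_rate(rates$p, t) - s) * L
}

#' Hamiltonian of the control problem
#'
#' \deqn{H = (p(t) - s)L - \lambda \left(u + \frac{h(t)}{1 + b(t)s}\right) L.}
#' The costate \eqn{\lambda} is the marginal value of leaf area (carbon per
#' area). For \eqn{\lambda \ge 0} the Hamiltonian is concave in `s`, so the
#' pointwise maximiser is unique; see [optimal_control()].
#'
#' @inheritParams leaf_rhs
#' @param lam Costate value (marginal value of leaf area).
#' @return Scalar (or vector) Hamiltonian value.
#' @export
hamiltonian <- function(L, lam, t, s, rates) {
  stopifnot(inherits(rates, "iso_rateset"))
  if (any(s < 0)) stop("production rate 's' must be non-negative")
  p <- eval_rate(rates$p, t)
  h <- eval_rate(rates$h, t)
  b <- eval_rate(rates$b_eff, t)
  (p - s) * L - lam * (rates$u + h / (1 + b * s)) * L
}
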