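#' Onset of the terminal no-production phase, constant rates
#'
#' With all rates constant, production ceases at the switching time
#' \deqn{t_s = T - \frac{1}{u + h}\,
#'   \ln\!\left(\frac{1}{1 - \frac{u + h}{p b h}}\right).}
#' Production is never profitable — the whole season is a zero phase — when
#' \eqn{p b h \le u + h} (the marginal benefit never exceeds the marginal
#' cost) or when the raw \eqn{t_s} is negative (the season is too short for
#' the value of leaf area to reach the production threshold). Both cases
#' return the no-production sentinel `NA`.
#'
#' @param p,h,b Positive constant photosynthetic rate, hazard, and
#'   isoprene effectiveness.
#' @param u Non-negative background loss rate.
#' @param T Positive season length.
#' @return The switching time in `(0, T)`, or `NA_real_` if isoprene
#'   production is never profitable.
#' @export
switching_time_constant <- function(p, h, b, u = 0, T = 1) {
  stopifnot(p > 0, h > 0, b > 0, u >= 0)
  if (T <= 0) stop("season length 'T' must be positive")
  if (p * b * h <= u + h) return(NA_real_)
  ts <- T - log(1 / (1 - (u + h) / (p * b * h))) / (u + h)
  if (ts < 0) NA_real_ else ts
}

#' Onset of the terminal no-production phase, general rates
#'
#' Solves the switching condition
#' \deqn{\frac{1}{b(t_s) h(t_s)} = \int_{t_s}^{T} p(t')\,
#'   \exp\!\left[-\int_{t_s}^{t'} (u + h(t''))\,dt''\right] dt'}
#' for \eqn{t_s}. The right-hand side is the per-area future net production
#' with zero control after \eqn{t_s}, which equals the zero-control costate
#' \eqn{\lambda_0(t_s)} (solving \eqn{d\lambda_0/dt = -p + \lambda_0(u + h)}
#' backward from \eqn{\lambda_0(T) = 0}); the residual
#' \eqn{\lambda_0(t) - 1/(b(t)h(t))} is scanned for sign changes on a fine
#' grid and the crossing is refined by bisection. If the residual never
#' becomes positive, production is never profitable and the sentinel `NA` is
#' returned. With several roots, the largest in `(0, T)` is the true
#' production cutoff; it is returned with attribute `multiple_roots = TRUE`.
#'
#' @param rates An [rate_set()].
#' @param params A [season_params()] (only `T` and `n_steps` are used).
#' @return Switching time in `(0, T)` or `NA_real_`.
#' @export
switching_time_general <- function(rates, params) {
  stopifnot(inherits(rates, "iso_rateset"), inherits(params, "iso_season"))
  # zero-control costate == RHS of the switching condition
  p0 <- season_params(T = params$T, L0 = params$L0, s_max = 0,
                      n_steps = params$n_steps)
  bw <- solve_backward(rates, p0)
  bh <- eval_rate(rates$b_eff, bw$t_grid) * eval_rate(rates$h, bw$t_grid)
  res <- bw$lam - 1 / bh
  sgn <- sign(res)
  cross <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  if (!length(cross)) {
    if (all(res <= 0)) return(NA_real_)
    # residual positive everywhere in (0,T): production profitable up to T
    # only if it crosses at T itself; lam(T)=0 forces res(T)<0, so this
    # cannot happen for positive rates.
    return(NA_real_)
  }
  lam_fun <- stats::splinefun(bw$t_grid, bw$lam, method = "natural")
  f <- function(t) {
    lam_fun(t) - 1 / (eval_rate(rates$b_eff, t) * eval_rate(rates$h, t))
  }
  refine <- function(i) {
    stats::uniroot(f, lower = bw$t_grid[i], upper = bw$t_grid[i + 1L],
                   tol = 1e-12)$root
  }
  root <- refine(cross[length(cross)])
  if (length(cross) > 1L) attr(root, "multiple_roots") <- TRUE
  root
}

#' Season-integrated heat stress
#'
#' \eqn{H_{total} = \int_0^T h(t)\,dt}, by adaptive quadrature at relative
#' tolerance `1e-8`. For the exponentially modulated cosine hazard this
#' equals \eqn{T e^{a_1} I_0(b_1)} (modified Bessel function), which the
#' test suite uses as an independent check.
#'
#' @param h An `iso_rate` hazard.
#' @param T Season length; defaults to the rate's own period.
#' @return The dimensionless integrated stress.
#' @export
total_heat_stress <- function(h, T = h$period) {
  stopifnot(inherits(h, "iso_rate"))
  stats::integrate(function(t) eval_rate(h, t), 0, T,
                   rel.tol = 1e-8, subdivisions = 200L)$value
}

#' Classify the control phases of a solved trajectory
#'
#' Labels every grid point of a solved trajectory as `max`
#' (\eqn{s = s_{max}}), `interior` (\eqn{0 < s < s_{max}}) or `zero`
#' (\eqn{s = 0}) using the threshold structure of [optimal_control()]:
#' the product \eqn{\lambda b h} is compared against 1 and
#' \eqn{(1 + b s_{max})^2}. Phase boundaries are refined between grid points
#' by bisection on the interpolated costate to `control_tol` in time. Under
#' constant rates the phase sequence must be max -> interior -> zero (any of
#' them possibly empty); a non-monotone sequence there signals a solver
#' fault and is an error.
#'
#' @param trajectory An `iso_trajectory` from [pmp_solve()].
#' @param s_max Maximum production rate; defaults to the trajectory's.
#' @param control_tol Time tolerance of the boundary bisection.
#' @return An object of class `iso_phases`: `has_production`, boundary times
#'   `t_phase1_end` (end of the max phase, `NA` if absent) and `t_s` (onset
#'   of the zero phase, `NA` if production continues to `T`), the run-length
#'   `sequence` of labels, and the per-point `labels`.
#' @export
classify_phases <- function(trajectory, s_max = trajectory$params$s_max,
                            control_tol = 1e-8) {
  stopifnot(inherits(trajectory, "iso_trajectory"))
  tg <- trajectory$t_grid
  x <- trajectory$lam * trajectory$b_vals * trajectory$h_vals
  upper <- (1 + trajectory$b_vals * s_max)^2
  eps <- 1e-9
  labels <- ifelse(x <= 1 + eps, "zero",
                   ifelse(x >= upper * (1 - eps), "max", "interior"))
  if (s_max == 0) labels[] <- "zero"
  runs <- rle(labels)
  seq_labels <- runs$values

  rates <- trajectory$rates
  constant <- rates$p$family == "constant" && rates$h$family == "constant" &&
    rates$b_eff$family == "constant"
  if (constant) {
    allowed <- c("max", "interior", "zero")
    if (anyDuplicated(seq_labels) ||
        any(diff(match(seq_labels, allowed)) < 0)) {
      stop("non-monotone phase sequence under constant rates: solver fault")
    }
  }

  lam_fun <- stats::splinefun(tg, trajectory$lam, method = "natural")
  boundary <- function(i, target_fun) {
    # bisect the crossing within [tg[i], tg[i+1]] to control_tol
    lo <- tg[i]; hi <- tg[i + 1L]
    g <- function(t) {
      b <- eval_rate(rates$b_eff, t); h <- eval_rate(rates$h, t)
      lam_fun(t) * b * h - target_fun(b)
    }
    glo <- g(lo); ghi <- g(hi)
    if (glo * ghi > 0) return((lo + hi) / 2)
    while (hi - lo > control_tol) {
      mid <- (lo + hi) / 2
      if (g(mid) * glo <= 0) hi <- mid else { lo <- mid; glo <- g(lo) }
    }
    (lo + hi) / 2
  }

  t_phase1_end <- NA_real_
  t_s <- NA_real_
  idx_max <- which(labels == "max")
  if (length(idx_max) && s_max > 0) {
    i <- max(idx_max)
    if (i < length(tg)) {
      t_phase1_end <- boundary(i, function(b) (1 + b * s_max)^2)
    } else t_phase1_end <- tg[length(tg)]
  }
  idx_pos <- which(labels != "zero")
  has_production <- length(idx_pos) > 0L
  if (has_production) {
    i <- max(idx_pos)
    t_s <- if (i < length(tg)) boundary(i, function(b) 1) else tg[length(tg)]
  }
  if (!is.na(t_phase1_end) && !is.na(t_s) && t_phase1_end > t_s) {
    stop("phase boundaries out of order: solver fault")
  }
  structure(list(has_production = has_production,
                 t_phase1_end = t_phase1_end, t_s = t_s,
                 sequence = seq_labels, labels = labels),
            class = "iso_phases")
}

#' @export
print.iso_phases <- function(x, ...) {
  cat("<iso_phases>", paste(x$sequence, collapse = " -> "), "\n")
  cat(sprintf("  t_phase1_end = %s, t_s = %s\n",
              format(x$t_phase1_end), format(x$t_s)))
  invisible(x)
}

# three-point quadratic interpolation of the argmax around grid index i
quad_peak <- function(t, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(t[i])
  d1 <- (y[i + 1L] - y[i - 1L]) / 2
  d2 <- y[i + 1L] - 2 * y[i] + y[i - 1L]
  if (d2 >= 0) return(t[i])
  t[i] - d1 / d2 * (t[2L] - t[1L])
}

#' Shift of the production peak relative to the stress peak
#'
#' Returns \eqn{\mathrm{argmax}\, s(t) - \mathrm{argmax}\, h(t)}. A
#' positive value means isoprene production peaks *after* the heat-stress
#' peak ("post-risk enhancement" of the marginal value of leaf area pushes
#' the optimal peak later when much leaf area is lost in the stress
#' period). Peaks are localised by three-point quadratic interpolation
#' around the grid maximum. A constant hazard or an all-zero schedule has
#' no defined peak and is an error.
#'
#' @param trajectory An `iso_trajectory`.
#' @return Signed time difference (days).
#' @export
peak_shift <- function(trajectory) {
  stopifnot(inherits(trajectory, "iso_trajectory"))
  h <- trajectory$h_vals
  if (diff(range(h)) <= 1e-12 * max(h)) {
    stop("peak undefined: hazard h(t) is constant")
  }
  if (all(trajectory$s <= 0)) stop("peak undefined: s is identically zero")
  quad_peak(trajectory$t_grid, trajectory$s) -
    quad_peak(trajectory$t_grid, h)
}

#' Elasticity of the initial production rate
#'
#' Proportional sensitivity \eqn{d \ln s(0) / d \ln \theta} of the initial
#' (and, with non-binding `s_max`, maximal) production rate to a scalar
#' model parameter, by central finite differences in log space: the
#' parameter is multiplied by \eqn{e^{\pm \delta}} and the model re-solved.
#' Intended for constant-rate baselines with `s_max` large enough that
#' `s(0) < s_max`. A Richardson check at half step is reported so callers
#' can verify numerical convergence.
#'
#' @param param_name One of `"p"`, `"h"`, `"b"`, `"u"`, `"T"`, `"L0"`.
#' @param base Named list of baseline constants: `p`, `h`, `b`, `u`, `T`,
#'   `s_max`, `L0` (optional, default 1), `n_steps` (optional).
#' @param rel_step Log-space step \eqn{\delta}; default `1e-3`.
#' @return An object of class `iso_elasticity`: `parameter`, `elasticity`,
#'   `rel_step`, `elasticity_half` (same estimate at `rel_step / 2`), and
#'   the baseline `s0`.
#' @export
elasticity <- function(param_name, base, rel_step = 1e-3) {
  param_name <- match.arg(param_name, c("p", "h", "b", "u", "T", "L0"))
  defaults <- list(L0 = 1, n_steps = 4000L)
  base <- utils::modifyList(defaults, base)
  needed <- c("p", "h", "b", "u", "T", "s_max")
  if (!all(needed %in% names(base))) {
    stop("'base' must provide ", paste(needed, collapse = ", "))
  }

  s0_at <- function(cfg) {
    rs <- rate_set(rate_constant(cfg$p, period = cfg$T),
                   rate_constant(cfg$h, period = cfg$T),
                   rate_constant(cfg$b, period = cfg$T), u = cfg$u)
    pr <- season_params(T = cfg$T, L0 = cfg$L0, s_max = cfg$s_max,
                        n_steps = cfg$n_steps)
    bw <- solve_backward(rs, pr)
    bw$s[1L]
  }
  s0 <- s0_at(base)
  if (s0 <= 0) stop("elasticity undefined: s(0) = 0 at the base configuration")
  if (s0 >= base$s_max * (1 - 1e-9)) {
    warning("s(0) is at s_max; elasticity reflects the binding constraint")
  }

  est <- function(delta) {
    up <- base; dn <- base
    up[[param_name]] <- base[[param_name]] * exp(delta)
    dn[[param_name]] <- base[[param_name]] * exp(-delta)
    (log(s0_at(up)) - log(s0_at(dn))) / (2 * delta)
  }
  if (base[[param_name]] == 0) {
    stop("log-space elasticity undefined for a zero-valued parameter")
  }
  structure(list(parameter = param_name, elasticity = est(rel_step),
                 rel_step = rel_step, elasticity_half = est(rel_step / 2),
                 s0 = s0),
            class = "iso_elasticity")
}

#' @export
print.iso_elasticity <- function(x, ...) {
  cat(sprintf("<iso_elasticity> d ln s(0) / d ln %s = %.4f (step %g, half-step %.4f)\n",
              x$parameter, x$elasticity, x$rel_step, x$elasticity_half))
  invisible(x)
}

#' Per-time decomposition of the marginal value of leaf area
#'
#' Tabulates, for every grid time, the immediate drivers of the optimal
#' control (current \eqn{\lambda}, \eqn{b}, \eqn{h} and their product
#' \eqn{\lambda b h} against the production thresholds) together with a
#' consistency check of the costate's interpretation: \eqn{\lambda(t)} must
#' equal the future net production per unit of current leaf area,
#' \deqn{\lambda(t) = \frac{1}{L(t)} \int_t^T (p - s) L\,dt',}
#' computed forward from the solved trajectory (the dynamics are linear in
#' `L`, so the exponential survival factor is `L(t')/L(t)`). A violation
#' beyond `tol` (relative to the costate's scale) signals an inconsistent
#' solver state and is an error.
#'
#' @param trajectory An `iso_trajectory`.
#' @param rates Rates; default the trajectory's own.
#' @param tol Relative tolerance of the identity check.
#' @return A `data.frame` with columns `t`, `lam`, `h`, `b`, `lam_bh`, `s`,
#'   `future_net_per_area`, `residual`.
#' @export
marginal_value_decomposition <- function(trajectory, rates = trajectory$rates,
                                         tol = 1e-3) {
  stopifnot(inherits(trajectory, "iso_trajectory"))
  tg <- trajectory$t_grid
  integrand <- (trajectory$p_vals - trajectory$s) * trajectory$L
  n <- length(tg)
  seg <- (integrand[-1L] + integrand[-n]) / 2 * diff(tg)
  future <- c(rev(cumsum(rev(seg))), 0) / trajectory$L
  residual <- trajectory$lam - future
  scale <- max(abs(trajectory$lam), 1e-12)
  if (max(abs(residual)) > tol * scale) {
    stop(sprintf(
      "costate identity violated: max |lam - future net production/area| = %g",
      max(abs(residual))))
  }
  data.frame(t = tg, lam = trajectory$lam, h = trajectory$h_vals,
             b = trajectory$b_vals,
             lam_bh = trajectory$lam * trajectory$b_vals * trajectory$h_vals,
             s = trajectory$s, future_net_per_area = future,
             residual = residual)
}
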