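#' Solver settings
#'
#' Numerical settings for the backward costate and forward state
#' integrations. The default integrator is a fixed-step classical
#' Runge--Kutta (RK4) scheme: the feedback control makes the costate
#' right-hand side continuous and piecewise smooth, so a fixed fine grid
#' handles the derivative kinks at control switches without step-size
#' control.
#'
#' @param integrator Only `"fixed_rk4"` is currently implemented.
#' @param n_steps Number of integration steps over the season (>= 100).
#' @param rel_tol Relative tolerance used in grid-convergence diagnostics.
#' @param control_tol Time tolerance for phase-boundary bisection (days).
#' @return An object of class `iso_solver`.
#' @export
solver_settings <- function(integrator = "fixed_rk4", n_steps = 20000L,
                            rel_tol = 1e-8, control_tol = 1e-8) {
  integrator <- match.arg(integrator, "fixed_rk4")
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 100L) stop("'n_steps' must be >= 100")
  if (rel_tol <= 0 || control_tol <= 0) stop("tolerances must be positive")
  structure(list(integrator = integrator, n_steps = n_steps,
                 rel_tol = rel_tol, control_tol = control_tol),
            class = "iso_solver")
}

# Raw optimal-control kernel on already-evaluated rates. Vectorised.
# Interior stationarity: (1 + b*s)^2 = lam*b*h; clamping to [0, s_max]
# reproduces both saturation thresholds of the piecewise law.
oc_kernel <- function(lam, b, h, s_max) {
  x <- lam * b * h
  s <- ifelse(x <= 1 | b <= 0, 0, (sqrt(pmax(x, 0)) - 1) / b)
  pmin(pmax(s, 0), s_max)
}

#' Optimal isoprene production rate
#'
#' The pointwise maximiser of the [hamiltonian()] over the admissible
#' control band \eqn{[0, s_{max}]}:
#' \deqn{\hat s(\lambda, t) = \begin{cases}
#'   0 & \lambda \le 1/(b h) \\
#'   \frac{1}{b}\left(\sqrt{\lambda b h} - 1\right)
#'     & 1/(b h) < \lambda < (1 + b s_{max})^2/(b h) \\
#'   s_{max} & \lambda \ge (1 + b s_{max})^2/(b h)
#' \end{cases}}
#' with \eqn{b = b(t)}, \eqn{h = h(t)}. The interior branch solves the
#' first-order condition \eqn{(1 + b\hat s)^2 = \lambda b h}; the upper
#' threshold is where the interior solution reaches \eqn{s_{max}}, making
#' \eqn{\hat s} continuous in \eqn{\lambda}. At the exact lower threshold
#' \eqn{\lambda b h = 1} the production is 0 (the boundary is closed on the
#' zero side). Marginal value \eqn{\lambda \le 0}, or a vanishing benefit
#' product \eqn{b h = 0}, gives \eqn{\hat s = 0}.
#'
#' @param lam Costate value(s), finite.
#' @param t Time(s) in `[0, T]`.
#' @param rates An [rate_set()].
#' @param s_max Maximum production rate (>= 0).
#' @return Production rate(s), clamped to `[0, s_max]`.
#' @export
optimal_control <- function(lam, t, rates, s_max) {
  stopifnot(inherits(rates, "iso_rateset"), all(is.finite(lam)), s_max >= 0)
  b <- eval_rate(rates$b_eff, t)
  h <- eval_rate(rates$h, t)
  oc_kernel(lam, b, h, s_max)
}

#' Costate dynamics with the feedback control substituted
#'
#' Right-hand side of the marginal-value ODE
#' \deqn{d\lambda/dt = -(p(t) - s) + \lambda\left(u +
#'   \frac{h(t)}{1 + b(t)s}\right),}
#' evaluated at \eqn{s = \hat s(\lambda, t)} from [optimal_control()]. It is
#' integrated backward from the terminal condition \eqn{\lambda(T) = 0}:
#' leaves are worthless at shedding.
#'
#' @inheritParams optimal_control
#' @return d\eqn{\lambda}/dt.
#' @export
costate_rhs <- function(lam, t, rates, s_max) {
  stopifnot(inherits(rates, "iso_rateset"), all(is.finite(lam)))
  p <- eval_rate(rates$p, t)
  h <- eval_rate(rates$h, t)
  b <- eval_rate(rates$b_eff, t)
  s <- oc_kernel(lam, b, h, s_max)
  -(p - s) + lam * (rates$u + h / (1 + b * s))
}

# Pre-evaluate all three rates on the integration grid and at step
# midpoints, so the RK4 loops are pure arithmetic.
tabulate_rates <- function(rates, t_grid) {
  n <- length(t_grid) - 1L
  t_mid <- (t_grid[-1L] + t_grid[-(n + 1L)]) / 2
  list(
    p_g = eval_rate(rates$p, t_grid), p_m = eval_rate(rates$p, t_mid),
    h_g = eval_rate(rates$h, t_grid), h_m = eval_rate(rates$h, t_mid),
    b_g = eval_rate(rates$b_eff, t_grid), b_m = eval_rate(rates$b_eff, t_mid),
    t_mid = t_mid
  )
}

#' Backward costate integration
#'
#' Integrates the costate ODE from `t = T` to `t = 0` with
#' \eqn{\lambda(T) = 0}, substituting the feedback control
#' \eqn{\hat s(\lambda, t)} at every internal RK4 stage (not frozen per
#' step). Returns \eqn{\lambda} and the induced control schedule on the
#' grid.
#'
#' @param rates An [rate_set()].
#' @param params A [season_params()].
#' @param settings A [solver_settings()]; defaults to the grid size in
#'   `params`.
#' @return List with `t_grid`, `lam`, `s` (all length `n_steps + 1`).
#' @export
solve_backward <- function(rates, params,
                           settings = solver_settings(n_steps = params$n_steps)) {
  stopifnot(inherits(rates, "iso_rateset"), inherits(params, "iso_season"))
  n <- settings$n_steps
  Tn <- params$T
  dt <- Tn / n
  t_grid <- seq(0, Tn, length.out = n + 1L)
  rt <- tabulate_rates(rates, t_grid)
  u <- rates$u
  smax <- params$s_max

  f <- function(lam, p, h, b) {
    s <- oc_kernel(lam, b, h, smax)
    -(p - s) + lam * (u + h / (1 + b * s))
  }

  lam <- numeric(n + 1L)
  lam[n + 1L] <- 0
  for (k in n:1L) {
    y <- lam[k + 1L]
    k1 <- f(y, rt$p_g[k + 1L], rt$h_g[k + 1L], rt$b_g[k + 1L])
    k2 <- f(y - dt / 2 * k1, rt$p_m[k], rt$h_m[k], rt$b_m[k])
    k3 <- f(y - dt / 2 * k2, rt$p_m[k], rt$h_m[k], rt$b_m[k])
    k4 <- f(y - dt * k3, rt$p_g[k], rt$h_g[k], rt$b_g[k])
    lam[k] <- y - dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(lam[k])) {
      stop(sprintf("costate integration diverged at t = %g (lambda non-finite)",
                   t_grid[k]))
    }
  }
  s <- oc_kernel(lam, rt$b_g, rt$h_g, smax)
  list(t_grid = t_grid, lam = lam, s = s)
}

# s may be: a function of t; or a numeric vector on t_grid (linearly
# interpolated at midpoints). Returns s at grid and midpoints.
schedule_on_grid <- function(s, t_grid, t_mid, s_max) {
  if (is.function(s)) {
    s_g <- s(t_grid)
    s_m <- s(t_mid)
  } else if (is.numeric(s) && length(s) == length(t_grid)) {
    s_g <- s
    s_m <- (s[-1L] + s[-length(s)]) / 2
  } else {
    stop("'s' must be a function of time or a numeric vector on the grid")
  }
  tol <- 1e-9 * max(s_max, 1)
  if (any(s_g < -tol | s_g > s_max + tol) ||
      any(s_m < -tol | s_m > s_max + tol)) {
    stop("schedule violates the control bounds [0, s_max]")
  }
  list(s_g = pmin(pmax(s_g, 0), s_max), s_m = pmin(pmax(s_m, 0), s_max))
}

#' Forward leaf-area integration under a given schedule
#'
#' Integrates the leaf-area ODE from `L(0) = L0` under an arbitrary
#' admissible production schedule, using the same fixed-step RK4 scheme as
#' the costate pass. The ODE is linear in `L`, so `L` stays strictly
#' positive and non-increasing.
#'
#' @param s Schedule: a function of time returning values in `[0, s_max]`,
#'   or a numeric vector on the integration grid.
#' @inheritParams solve_backward
#' @return List with `t_grid`, `L`, and `s` evaluated on the grid.
#' @export
solve_forward <- function(s, rates, params,
                          settings = solver_settings(n_steps = params$n_steps)) {
  stopifnot(inherits(rates, "iso_rateset"), inherits(params, "iso_season"))
  n <- settings$n_steps
  Tn <- params$T
  dt <- Tn / n
  t_grid <- seq(0, Tn, length.out = n + 1L)
  rt <- tabulate_rates(rates, t_grid)
  sch <- schedule_on_grid(s, t_grid, rt$t_mid, params$s_max)
  u <- rates$u

  # decay rate u + h/(1+bs) at grid and midpoints
  r_g <- u + rt$h_g / (1 + rt$b_g * sch$s_g)
  r_m <- u + rt$h_m / (1 + rt$b_m * sch$s_m)

  L <- numeric(n + 1L)
  L[1L] <- params$L0
  for (k in 1:n) {
    y <- L[k]
    k1 <- -r_g[k] * y
    k2 <- -r_m[k] * (y + dt / 2 * k1)
    k3 <- -r_m[k] * (y + dt / 2 * k2)
    k4 <- -r_g[k + 1L] * (y + dt * k3)
    L[k + 1L] <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(t_grid = t_grid, L = L, s = sch$s_g)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' Season objective
#'
#' Trapezoid-rule quadrature of the net photosynthesis
#' \eqn{\phi = \int_0^T (p(t) - s(t)) L(t)\,dt} on the solver grid. The
#' trapezoid rule matches the effective order of the composed scheme at the
#' control-switch kinks.
#'
#' @param trajectory A solved [pmp_solve()] trajectory, or any list with
#'   `t_grid`, `L`, `s` components.
#' @param rates An [rate_set()].
#' @return The objective \eqn{\phi} in carbon units.
#' @export
evaluate_objective <- function(trajectory, rates) {
  stopifnot(inherits(rates, "iso_rateset"))
  tg <- trajectory$t_grid
  p <- eval_rate(rates$p, tg)
  trapz(tg, (p - trajectory$s) * trajectory$L)
}

#' Solve the full seasonal optimal-control problem
#'
#' Composes the three passes of the maximum-principle solution:
#' backward costate integration ([solve_backward()]), forward leaf-area
#' integration under the resulting optimal schedule ([solve_forward()]),
#' and objective quadrature ([evaluate_objective()]).
#'
#' @inheritParams solve_backward
#' @return An object of class `iso_trajectory`: a list with `t_grid`, `L`,
#'   `lam`, `s`, the evaluated rates `p_vals`, `h_vals`, `b_vals`, the
#'   Hamiltonian `H_vals` along the solution, the objective `phi`, and the
#'   `rates`/`params`/`settings` used.
#' @examples
#' rs <- rate_set(rate_constant(1), rate_constant(2), rate_constant(2),
#'                u = 1e-4)
#' tr <- pmp_solve(rs, season_params(s_max = 0.132, n_steps = 2000))
#' tr$phi
#' @export
pmp_solve <- function(rates, params,
                      settings = solver_settings(n_steps = params$n_steps)) {
  bw <- solve_backward(rates, params, settings)
  # the optimal schedule as a function of t, via the interpolated costate
  lam_fun <- stats::splinefun(bw$t_grid, bw$lam, method = "natural")
  s_fun <- function(t) optimal_control(lam_fun(t), t, rates, params$s_max)
  fw <- solve_forward(s_fun, rates, params, settings)

  tg <- bw$t_grid
  p_vals <- eval_rate(rates$p, tg)
  h_vals <- eval_rate(rates$h, tg)
  b_vals <- eval_rate(rates$b_eff, tg)
  H_vals <- (p_vals - bw$s) * fw$L -
    bw$lam * (rates$u + h_vals / (1 + b_vals * bw$s)) * fw$L
  traj <- structure(
    list(t_grid = tg, L = fw$L, lam = bw$lam, s = bw$s,
         p_vals = p_vals, h_vals = h_vals, b_vals = b_vals,
         H_vals = H_vals, phi = trapz(tg, (p_vals - bw$s) * fw$L),
         rates = rates, params = params, settings = settings),
    class = "iso_trajectory")
  validate_trajectory(traj)
  traj
}

validate_trajectory <- function(traj) {
  with(traj, {
    n <- length(t_grid)
    stopifnot(length(L) == n, length(lam) == n, length(s) == n)
    if (any(s < 0 | s > params$s_max + 1e-12)) {
      stop("trajectory invariant violated: s outside [0, s_max]")
    }
    if (any(L <= 0)) stop("trajectory invariant violated: L not positive")
    if (any(diff(L) > 1e-12 * L[1L])) {
      stop("trajectory invariant violated: L increasing")
    }
    if (lam[n] != 0) stop("trajectory invariant violated: lam(T) != 0")
  })
  invisible(traj)
}

#' @export
print.iso_trajectory <- function(x, ...) {
  cat(sprintf(
    "<iso_trajectory> %d grid points on [0, %g]\n  phi = %.6g, L(T)/L0 = %.4f, max s = %.4g (s_max = %g)\n",
    length(x$t_grid), x$params$T, x$phi, x$L[length(x$L)] / x$params$L0,
    max(x$s), x$params$s_max))
  invisible(x)
}
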