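#' Piecewise-constant schedule as a function of time
#'
#' Builds the step function taking value `levels[i]` on the i-th of
#' `length(levels)` equal bins of `[0, T]` (right-continuous; the final bin
#' is closed at `T`).
#'
#' @param levels Numeric vector of production levels.
#' @param T Season length.
#' @return A function of time.
#' @export
schedule_fun <- function(levels, T = 1) {
  n <- length(levels)
  function(t) levels[pmin(pmax(floor(t / (T / n)) + 1L, 1L), n)]
}

# Objective of an arbitrary schedule, via the canonical forward integrator.
schedule_phi <- function(s, rates, params, settings) {
  fw <- solve_forward(s, rates, params, settings)
  evaluate_objective(fw, rates)
}

# Per-bin survival factor d and per-unit-start-area gain g for every
# (bin, level) pair, using the same RK4 stepper + trapezoid quadrature as
# the main solver restricted to one bin. The leaf dynamics are linear in L,
# so the objective of any piecewise-constant schedule decomposes exactly as
#   phi = L0 * sum_i g[i, l_i] * prod_{j<i} d[j, l_j].
bin_factors <- function(rates, params, n_bins, levels, steps_per_bin) {
  Tn <- params$T
  width <- Tn / n_bins
  nl <- length(levels)
  g <- matrix(0, n_bins, nl)
  d <- matrix(0, n_bins, nl)
  for (i in seq_len(n_bins)) {
    t_sub <- seq((i - 1) * width, i * width, length.out = steps_per_bin + 1L)
    rt <- tabulate_rates(rates, t_sub)
    dt <- width / steps_per_bin
    for (l in seq_len(nl)) {
      s <- levels[l]
      r_g <- rates$u + rt$h_g / (1 + rt$b_g * s)
      r_m <- rates$u + rt$h_m / (1 + rt$b_m * s)
      L <- numeric(steps_per_bin + 1L)
      L[1L] <- 1
      for (k in seq_len(steps_per_bin)) {
        y <- L[k]
        k1 <- -r_g[k] * y
        k2 <- -r_m[k] * (y + dt / 2 * k1)
        k3 <- -r_m[k] * (y + dt / 2 * k2)
        k4 <- -r_g[k + 1L] * (y + dt * k3)
        L[k + 1L] <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      g[i, l] <- trapz(t_sub, (rt$p_g - s) * L)
      d[i, l] <- L[steps_per_bin + 1L]
    }
  }
  list(g = g, d = d)
}

#' Direct discretized optimization of the production schedule
#'
#' Independent brute-force validation of the maximum-principle solution:
#' searches all piecewise-constant schedules on `n_bins` equal time bins
#' with `n_levels` equally spaced production levels in `[0, s_max]`, every
#' candidate evaluated with the same forward integrator and quadrature as
#' the main solver. In `"exhaustive"` mode the search is exact over all
#' `n_levels^n_bins` candidates: because the leaf dynamics are linear in
#' `L`, the objective factorises across bins, so backward induction over
#' bins finds the global discrete optimum at `n_bins * n_levels` bin
#' integrations. `"coordinate"` mode runs coordinate ascent on the same
#' factorisation for larger bin counts.
#'
#' @param rates An [rate_set()].
#' @param params A [season_params()].
#' @param n_bins Number of equal time bins.
#' @param n_levels Number of equally spaced control levels.
#' @param mode `"exhaustive"` (exact, `n_bins <= 12`) or `"coordinate"`.
#' @param n_steps_fine Total fine-grid steps for candidate evaluation
#'   (rounded up to a multiple of `n_bins`).
#' @return An object of class `iso_oracle`: `n_bins`, `n_levels`,
#'   `best_schedule` (levels per bin), `phi_oracle` (objective of the best
#'   schedule re-evaluated by a full-season forward solve), `n_eval`
#'   (bin integrations performed), `n_candidates` (size of the searched
#'   schedule space), `mode`.
#' @export
direct_optimize <- function(rates, params, n_bins = 8L, n_levels = 9L,
                            mode = c("exhaustive", "coordinate"),
                            n_steps_fine = 4000L) {
  stopifnot(inherits(rates, "iso_rateset"), inherits(params, "iso_season"))
  mode <- match.arg(mode)
  n_bins <- as.integer(n_bins)
  n_levels <- as.integer(n_levels)
  if (mode == "exhaustive" && n_bins > 12L) {
    stop("exhaustive mode supports n_bins <= 12; use mode = \"coordinate\"")
  }
  levels <- if (params$s_max > 0 && n_levels > 1L) {
    seq(0, params$s_max, length.out = n_levels)
  } else 0
  n_levels <- length(levels)
  steps_per_bin <- max(ceiling(n_steps_fine / n_bins), 10L)
  bf <- bin_factors(rates, params, n_bins, levels, steps_per_bin)

  if (mode == "exhaustive") {
    # backward induction: V_i = max_l g[i,l] + d[i,l] * V_{i+1}
    V <- 0
    pick <- integer(n_bins)
    for (i in n_bins:1L) {
      vals <- bf$g[i, ] + bf$d[i, ] * V
      pick[i] <- which.max(vals)
      V <- vals[pick[i]]
    }
  } else {
    pick <- rep((n_levels + 1L) %/% 2L, n_bins)
    phi_of <- function(pk) {
      surv <- cumprod(c(1, bf$d[cbind(seq_len(n_bins), pk)]))[seq_len(n_bins)]
      sum(bf$g[cbind(seq_len(n_bins), pk)] * surv)
    }
    best <- phi_of(pick)
    for (sweep in seq_len(100L)) {
      changed <- FALSE
      for (i in seq_len(n_bins)) {
        cand <- pick
        vals <- vapply(seq_len(n_levels), function(l) {
          cand[i] <- l; phi_of(cand)
        }, numeric(1))
        l_best <- which.max(vals)
        if (vals[l_best] > best + 1e-15) {
          pick[i] <- l_best; best <- vals[l_best]; changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  best_schedule <- levels[pick]
  settings <- solver_settings(n_steps = steps_per_bin * n_bins)
  phi_oracle <- schedule_phi(schedule_fun(best_schedule, params$T),
                             rates, params, settings)
  structure(list(n_bins = n_bins, n_levels = n_levels,
                 best_schedule = best_schedule, phi_oracle = phi_oracle,
                 n_eval = n_bins * n_levels,
                 n_candidates = n_levels^n_bins, mode = mode),
            class = "iso_oracle")
}

#' @export
print.iso_oracle <- function(x, ...) {
  cat(sprintf(
    "<iso_oracle> %s search over %d bins x %d levels (%.3g candidates)\n  phi_oracle = %.8g\n  best schedule: %s\n",
    x$mode, x$n_bins, x$n_levels, x$n_candidates, x$phi_oracle,
    paste(signif(x$best_schedule, 4), collapse = " ")))
  invisible(x)
}

#' Dominance test of a candidate optimal trajectory
#'
#' Checks the maximality claim directly: the objective of the supplied
#' trajectory's schedule must (weakly) dominate `n_random` seeded random
#' piecewise-constant feasible schedules plus `n_perturb` local
#' perturbations of the schedule itself (a bump of `+/- eps` on a random
#' subinterval of width `width`, clamped to the control bounds). All
#' objectives, including the reference, are evaluated with the same forward
#' integrator at `n_steps` so that comparisons isolate the control law.
#'
#' @param trajectory An `iso_trajectory` (or any list with `t_grid` and `s`).
#' @param rates An [rate_set()].
#' @param params A [season_params()].
#' @param n_random Number of random schedules (>= 100).
#' @param seed RNG seed (logged in the report).
#' @param n_perturb Number of local perturbations of the schedule.
#' @param eps Perturbation magnitude; default `0.05 * s_max`.
#' @param width Perturbation window; default `0.05 * T`.
#' @param n_steps Evaluation grid for all candidates. The default matches
#'   the main solver: local perturbations change the objective only at
#'   second order in `eps`, so the evaluation grid must be fine enough that
#'   integrator noise stays below that margin.
#' @param tol Allowed violation, default `1e-8`.
#' @return An object of class `iso_dominance`: `pass`, `phi_ref`,
#'   `worst_margin` (min over candidates of `phi_ref - phi_candidate`),
#'   `n_checked`, `seed`, and — on failure — `worst_candidate`, the
#'   offending schedule function's description.
#' @export
dominance_test <- function(trajectory, rates, params, n_random = 500L,
                           seed = 1L, n_perturb = 50L,
                           eps = 0.05 * params$s_max,
                           width = 0.05 * params$T, n_steps = 20000L,
                           tol = 1e-8) {
  stopifnot(n_random >= 100L)
  settings <- solver_settings(n_steps = n_steps)
  s_ref <- stats::approxfun(trajectory$t_grid, trajectory$s, rule = 2)
  phi_ref <- schedule_phi(function(t) pmin(pmax(s_ref(t), 0), params$s_max),
                          rates, params, settings)
  set.seed(seed)
  worst_margin <- Inf
  worst_candidate <- NULL
  n_checked <- 0L
  consider <- function(s_fun, label) {
    phi_c <- schedule_phi(s_fun, rates, params, settings)
    margin <- phi_ref - phi_c
    n_checked <<- n_checked + 1L
    if (margin < worst_margin) {
      worst_margin <<- margin
      worst_candidate <<- label
    }
  }
  for (i in seq_len(n_random)) {
    nb <- sample(4:16, 1L)
    lv <- stats::runif(nb, 0, params$s_max)
    consider(schedule_fun(lv, params$T),
             sprintf("random piecewise-constant #%d (%d bins)", i, nb))
  }
  for (i in seq_len(n_perturb)) {
    t0 <- stats::runif(1, 0, params$T - width)
    dir <- sample(c(-1, 1), 1L)
    s_p <- function(t) {
      base <- pmin(pmax(s_ref(t), 0), params$s_max)
      bump <- ifelse(t >= t0 & t <= t0 + width, dir * eps, 0)
      pmin(pmax(base + bump, 0), params$s_max)
    }
    consider(s_p, sprintf("local %+g bump on [%0.4f, %0.4f]",
                          dir * eps, t0, t0 + width))
  }
  pass <- worst_margin >= -tol
  structure(list(pass = pass, phi_ref = phi_ref, worst_margin = worst_margin,
                 n_checked = n_checked, seed = seed,
                 worst_candidate = if (pass) NULL else worst_candidate),
            class = "iso_dominance")
}

#' @export
print.iso_dominance <- function(x, ...) {
  cat(sprintf(
    "<iso_dominance> %s: %d candidates, phi_ref = %.8g, worst margin = %.3g (seed %d)\n",
    if (x$pass) "PASS" else "FAIL", x$n_checked, x$phi_ref, x$worst_margin,
    x$seed))
  if (!is.null(x$worst_candidate)) {
    cat("  beaten by:", x$worst_candidate, "\n")
  }
  invisible(x)
}
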