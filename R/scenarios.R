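#' A non-binding production cap
#'
#' Several seasonal scenarios state no explicit cap on the daily isoprene
#' production; their qualitative claims concern the interior (unsaturated)
#' solution. This helper solves the costate pass once with an effectively
#' unbounded control and returns ten times the largest production rate
#' encountered, so that the returned `s_max` can never bind.
#'
#' @param rates An [rate_set()].
#' @param T Season length.
#' @param n_steps Grid used for the probe solve.
#' @return A positive scalar cap.
#' @export
nonbinding_smax <- function(rates, T = rates$period, n_steps = 4000L) {
  probe <- season_params(T = T, L0 = 1, s_max = 1e6, n_steps = n_steps)
  bw <- solve_backward(rates, probe)
  m <- max(bw$s)
  if (m <= 0) 1 else 10 * m
}

#' Built-in seasonal scenarios
#'
#' The canonical model configurations, keyed by the seasonal pattern they
#' explore:
#'
#' * `fig2_constant` — all rates constant (`p = 1`, `h = 2`, `b = 2`,
#'   `u = 1e-4`, `T = 1`, `s_max = 0.132`): the three-phase schedule.
#' * `fig3_heat_peak` — midsummer hazard peak,
#'   `h(t) = exp[-cos(2 pi t / T)]`, `s_max = 0.155`.
#' * `fig4_heat_peak_sweep` — as `fig3` but sweeping the hazard shape
#'   factor `b1` in {1, 2, 4} with a non-binding `s_max`: the post-risk
#'   enhancement cases.
#' * `fig5a_photo_peak` — midsummer photosynthesis peak,
#'   `p(t) = exp[-0.5 cos(2 pi t / T)]`, constant hazard.
#' * `fig5b_volatility_drop` — midsummer effectiveness dip,
#'   `b(t) = 0.5 exp[0.5 cos(2 pi t / T)]` (volatility loss of the
#'   compound in summer heat).
#'
#' @param name Scenario name (see above).
#' @param b1 Hazard shape factor for `fig4_heat_peak_sweep` (default 4).
#' @param n_steps Solver grid resolution.
#' @param s_max Optional override of the production cap; scenarios without
#'   a stated cap default to [nonbinding_smax()].
#' @return A list with `name`, `rates` ([rate_set()]), `params`
#'   ([season_params()]) and, for the sweep scenario, `b1`.
#' @export
get_scenario <- function(name, b1 = 4, n_steps = 20000L, s_max = NULL) {
  name <- match.arg(name, scenario_names())
  Tn <- 1
  u <- 1e-4
  const1 <- rate_constant(1, period = Tn)
  const2 <- rate_constant(2, period = Tn)
  sc <- switch(
    name,
    fig2_constant = list(
      rates = rate_set(const1, const2, const2, u = u),
      s_max_default = 0.132),
    fig3_heat_peak = list(
      rates = rate_set(const1, rate_exp_cosine(0, 1, period = Tn),
                       const2, u = u),
      s_max_default = 0.155),
    fig4_heat_peak_sweep = list(
      rates = rate_set(const1, rate_exp_cosine(0, b1, period = Tn),
                       const2, u = u),
      s_max_default = NULL),
    fig5a_photo_peak = list(
      rates = rate_set(rate_exp_cosine(0, 0.5, period = Tn), const2,
                       const2, u = u),
      s_max_default = NULL),
    fig5b_volatility_drop = list(
      rates = rate_set(const1, const2,
                       rate_exp_cosine(0, 0.5, scale = 0.5, sign = 1,
                                       period = Tn),
                       u = u),
      s_max_default = NULL))
  if (is.null(s_max)) {
    s_max <- sc$s_max_default
    if (is.null(s_max)) s_max <- nonbinding_smax(sc$rates, Tn)
  }
  out <- list(name = name, rates = sc$rates,
              params = season_params(T = Tn, L0 = 1, s_max = s_max,
                                     n_steps = n_steps))
  if (name == "fig4_heat_peak_sweep") out$b1 <- b1
  out
}

#' @rdname get_scenario
#' @export
scenario_names <- function() {
  c("fig2_constant", "fig3_heat_peak", "fig4_heat_peak_sweep",
    "fig5a_photo_peak", "fig5b_volatility_drop")
}
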