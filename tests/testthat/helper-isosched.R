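# shared fixtures; built in code, moderate grids keep the suite fast

const_rates <- function(p = 1, h = 2, b = 2, u = 1e-4, T = 1) {
  rate_set(rate_constant(p, period = T), rate_constant(h, period = T),
           rate_constant(b, period = T), u = u)
}

fig2_rates <- function() const_rates()

fig2_params <- function(n_steps = 4000L) {
  season_params(T = 1, L0 = 1, s_max = 0.132, n_steps = n_steps)
}

fig4_case <- function(b1, n_steps = 4000L) {
  get_scenario("fig4_heat_peak_sweep", b1 = b1, n_steps = n_steps)
}

solve_fig2 <- local({
  cache <- NULL
  function(n_steps = 4000L) {
    key <- as.character(n_steps)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- pmp_solve(fig2_rates(), fig2_params(n_steps))
    }
    cache[[key]]
  }
})

# closed-form zero-control objective phi = L0 p (1 - e^{-(u+h)T}) / (u+h)
phi_zero_control <- function(p = 1, h = 2, u = 1e-4, T = 1, L0 = 1) {
  L0 * p * (1 - exp(-(u + h) * T)) / (u + h)
}

# interpolated time of the production peak of a solved trajectory
quad_peak_time <- function(tr) isosched:::quad_peak(tr$t_grid, tr$s)

# brute-force argmax of the Hamiltonian on an s-grid
grid_argmax_control <- function(lam, t, rates, s_max, n_grid = 1001L) {
  sg <- seq(0, s_max, length.out = n_grid)
  sg[which.max(hamiltonian(1, lam, t, sg, rates))]
}
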