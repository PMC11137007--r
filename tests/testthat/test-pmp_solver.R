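test_that("optimal control reproduces the piecewise law", {
  rs <- fig2_rates()  # b = h = 2, so b*h = 4
  expect_equal(optimal_control(0.2, 0.1, rs, 1), 0)       # lam <= 1/(bh)
  expect_equal(optimal_control(0.25, 0.1, rs, 1), 0)      # tie: zero side
  expect_equal(optimal_control(1, 0.1, rs, 1), 0.5, tolerance = 1e-12)
  expect_equal(optimal_control(10, 0.1, rs, 0.132), 0.132) # saturated
  expect_equal(optimal_control(-3, 0.1, rs, 1), 0)         # worthless leaves
  # continuity at the saturation threshold lam = (1 + b s_max)^2 / (b h)
  smax <- 0.132
  lam_c <- (1 + 2 * smax)^2 / 4
  expect_equal(optimal_control(lam_c, 0.1, rs, smax), smax, tolerance = 1e-12)
  expect_equal(optimal_control(lam_c - 1e-9, 0.1, rs, smax), smax,
               tolerance = 1e-6)
})

test_that("optimal control maximizes the Hamiltonian (grid oracle)", {
  set.seed(3)
  cases <- list(
    list(rates = fig2_rates(), s_max = 0.132),
    list(rates = get_scenario("fig3_heat_peak", n_steps = 1000)$rates,
         s_max = 0.155),
    list(rates = fig4_case(4, 1000)$rates, s_max = 2))
  for (cs in cases) {
    for (i in 1:60) {
      lam <- runif(1, 0, 2); t <- runif(1, 0, 1)
      s_hat <- optimal_control(lam, t, cs$rates, cs$s_max)
      s_grid <- grid_argmax_control(lam, t, cs$rates, cs$s_max)
      expect_lt(abs(s_hat - s_grid), 1e-3 * cs$s_max)
      # and dominates every grid point
      sg <- seq(0, cs$s_max, length.out = 1001)
      expect_gte(hamiltonian(1, lam, t, s_hat, cs$rates),
                 max(hamiltonian(1, lam, t, sg, cs$rates)) - 1e-10)
    }
  }
})

test_that("costate RHS substitutes the feedback control", {
  rs <- fig2_rates()
  expect_equal(costate_rhs(0, 0.5, rs, 1), -1, tolerance = 1e-12)
  # stationary point of the costate ODE with u=0, p=1, h=b=2:
  # s_hat = 0.25, lam = (1 + b s_hat)^2/(b h) = 0.5625, so
  # -(1 - 0.25) + 0.5625 * 2/1.5 = 0
  rs0 <- const_rates(u = 0)
  expect_equal(costate_rhs(0.5625, 0.5, rs0, 1), 0, tolerance = 1e-12)
  # zero-production band: -p + lam (u + h)
  lam <- 0.2  # lam*b*h = 0.8 < 1
  expect_equal(costate_rhs(lam, 0.5, rs, 1), -1 + lam * 2.0001,
               tolerance = 1e-12)
})

test_that("backward pass matches the closed-form costate in the zero phase", {
  bw <- solve_backward(fig2_rates(), fig2_params(4000))
  expect_equal(bw$lam[length(bw$lam)], 0)
  uh <- 2.0001
  lam_cf <- (1 - exp(-uh * (1 - bw$t_grid))) / uh
  zero_phase <- bw$t_grid > 0.66  # strictly inside the s = 0 phase
  expect_equal(bw$lam[zero_phase], lam_cf[zero_phase], tolerance = 1e-9)
  expect_true(all(bw$lam >= 0))
  expect_true(all(bw$s >= 0 & bw$s <= 0.132))
  # negligible photosynthesis: nothing worth protecting
  rs_tiny <- const_rates(p = 1e-9)
  bw0 <- solve_backward(rs_tiny, fig2_params(1000))
  expect_true(all(bw0$s == 0))
  expect_lt(max(bw0$lam), 1e-8)
})

test_that("forward pass integrates exponential-decay closed forms", {
  rs <- fig2_rates()
  pr <- fig2_params(2000)
  fw0 <- solve_forward(function(t) rep(0, length(t)), rs, pr)
  expect_equal(fw0$L, exp(-2.0001 * fw0$t_grid), tolerance = 1e-10)
  fwm <- solve_forward(function(t) rep(0.132, length(t)), rs, pr)
  expect_equal(fwm$L, exp(-(1e-4 + 2 / (1 + 2 * 0.132)) * fwm$t_grid),
               tolerance = 1e-10)
  expect_error(solve_forward(function(t) rep(0.2, length(t)), rs, pr),
               "control bounds")
  expect_error(season_params(L0 = 0), "positive") # degenerate start rejected
})

test_that("objective quadrature matches the zero-control closed form", {
  rs <- fig2_rates()
  pr <- fig2_params(2000)
  fw0 <- solve_forward(function(t) rep(0, length(t)), rs, pr)
  # trapezoid error at 2000 steps is O(dt^2) ~ 4e-8
  expect_equal(evaluate_objective(fw0, rs), phi_zero_control(),
               tolerance = 1e-6)
  # p identically equal to s: gain exactly cancels cost
  pr1 <- season_params(s_max = 1, n_steps = 2000)
  fw1 <- solve_forward(function(t) rep(1, length(t)), rs, pr1)
  expect_equal(evaluate_objective(fw1, rs), 0, tolerance = 1e-12)
})

test_that("full solve satisfies the trajectory invariants and linearity in L0", {
  tr <- solve_fig2(4000)
  expect_s3_class(tr, "iso_trajectory")
  expect_equal(tr$lam[length(tr$lam)], 0)
  expect_true(all(diff(tr$L) < 0))
  expect_gt(tr$phi, phi_zero_control())  # producing isoprene pays off
  # doubling L0 doubles phi, leaves s and lam unchanged
  tr2 <- pmp_solve(fig2_rates(),
                   season_params(L0 = 2, s_max = 0.132, n_steps = 4000))
  expect_equal(tr2$phi, 2 * tr$phi, tolerance = 1e-12)
  expect_equal(tr2$s, tr$s, tolerance = 1e-12)
  expect_equal(tr2$lam, tr$lam, tolerance = 1e-12)
  # s_max = 0 forces the zero-control solution
  tr0 <- pmp_solve(fig2_rates(), season_params(s_max = 0, n_steps = 2000))
  expect_true(all(tr0$s == 0))
  expect_equal(tr0$phi, phi_zero_control(), tolerance = 1e-6)
})

test_that("halving the step changes phi below the relative tolerance", {
  phi_a <- pmp_solve(fig2_rates(), fig2_params(10000))$phi
  phi_b <- pmp_solve(fig2_rates(), fig2_params(20000))$phi
  expect_lt(abs(phi_a - phi_b), 1e-8 * abs(phi_b))
})

test_that("interior stationarity holds along the solved trajectory", {
  tr <- solve_fig2(4000)
  interior <- tr$s > 1e-6 & tr$s < 0.132 - 1e-6
  lhs <- (1 + tr$b_vals[interior] * tr$s[interior])^2
  rhs <- tr$lam[interior] * tr$b_vals[interior] * tr$h_vals[interior]
  expect_equal(lhs, rhs, tolerance = 1e-9)
})
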