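test_that("constant-rate switching time matches its closed form and sentinels", {
  # frozen from the closed form evaluated in high precision
  expect_equal(switching_time_constant(1, 2, 2, 1e-4, 1), 0.653418738158099,
               tolerance = 1e-12)
  # unprofitable: p b h <= u + h
  expect_true(is.na(switching_time_constant(1, 2, 0.5, 1e-4, 1)))
  # season too short: raw t_s < 0
  expect_true(is.na(switching_time_constant(1, 2, 2, 1e-4, 0.1)))
  expect_error(switching_time_constant(1, 2, 2, 1e-4, 0), "positive")
  # cross-check against the backward solution: lam(t_s) b h = 1
  bw <- solve_backward(fig2_rates(), fig2_params(8000))
  lam_ts <- stats::splinefun(bw$t_grid, bw$lam)(0.653418738158099)
  expect_equal(lam_ts * 4, 1, tolerance = 1e-6)
})

test_that("general switching condition agrees with the closed form and scans", {
  ts_gen <- switching_time_general(fig2_rates(), fig2_params(8000))
  expect_equal(as.numeric(ts_gen), switching_time_constant(1, 2, 2, 1e-4, 1),
               tolerance = 1e-6)
  # seasonal hazard: agrees with the full solve's last lam*b*h = 1 crossing
  sc <- get_scenario("fig3_heat_peak", n_steps = 8000)
  ts3 <- switching_time_general(sc$rates, sc$params)
  tr3 <- pmp_solve(sc$rates, sc$params)
  expect_equal(as.numeric(ts3), classify_phases(tr3)$t_s, tolerance = 1e-4)
  # negligible photosynthesis: never profitable
  expect_true(is.na(switching_time_general(const_rates(p = 1e-9),
                                           fig2_params(1000))))
})

test_that("t_s increases with p, h and b under constant rates", {
  base <- c(p = 1, h = 2, b = 2)
  for (par in names(base)) {
    vals <- vapply(c(1, 1.5, 2, 3), function(f) {
      a <- as.list(base); a[[par]] <- base[[par]] * f
      switching_time_constant(a$p, a$h, a$b, 1e-4, 1)
    }, numeric(1))
    expect_true(all(diff(vals) > 0), info = par)
  }
})

test_that("integrated heat stress matches quadrature oracles", {
  expect_equal(total_heat_stress(rate_constant(2), 1), 2, tolerance = 1e-8)
  # closed form for the exp-cosine family: T * exp(a1) * I0(b1)
  for (b1 in c(0.5, 1, 2, 4)) {
    expect_equal(total_heat_stress(rate_exp_cosine(0, b1)),
                 besselI(b1, 0), tolerance = 1e-8)
  }
  expect_equal(total_heat_stress(rate_exp_cosine(0.3, 1.5, period = 2)),
               2 * exp(0.3) * besselI(1.5, 0), tolerance = 1e-8)
  h_tot <- vapply(c(1, 2, 3, 4), function(b1) {
    total_heat_stress(rate_exp_cosine(0, b1))
  }, numeric(1))
  expect_true(all(diff(h_tot) > 0))  # increasing in the shape factor
})

test_that("phase classification finds the three ordered phases", {
  tr <- solve_fig2(4000)
  ph <- classify_phases(tr)
  expect_identical(ph$sequence, c("max", "interior", "zero"))
  expect_true(ph$has_production)
  expect_lt(ph$t_phase1_end, ph$t_s)
  expect_equal(ph$t_s, 0.653418738158099, tolerance = 1e-5)
  # large s_max: no saturated phase
  tr_big <- pmp_solve(fig2_rates(), season_params(s_max = 10, n_steps = 2000))
  ph_big <- classify_phases(tr_big)
  expect_identical(ph_big$sequence, c("interior", "zero"))
  expect_true(is.na(ph_big$t_phase1_end))
  # negligible photosynthesis: one zero phase over the whole season
  tr0 <- pmp_solve(const_rates(p = 1e-9), fig2_params(1000))
  ph0 <- classify_phases(tr0)
  expect_identical(ph0$sequence, "zero")
  expect_false(ph0$has_production)
  expect_true(is.na(ph0$t_s))
})

test_that("production peaks after the stress peak, more so under stronger stress", {
  shifts <- vapply(c(1, 2, 4), function(b1) {
    sc <- fig4_case(b1)
    peak_shift(pmp_solve(sc$rates, sc$params))
  }, numeric(1))
  expect_true(all(diff(shifts) > 0))     # monotone in total stress
  expect_gt(shifts[3], 0)                # clear post-risk enhancement at b1=4
  expect_gt(shifts[3], shifts[1])
  # undefined peaks are errors
  expect_error(peak_shift(solve_fig2(4000)), "constant")
  tr0 <- pmp_solve(rate_set(rate_constant(1e-9),
                            rate_exp_cosine(0, 1), rate_constant(2), u = 1e-4),
                   fig2_params(1000))
  expect_error(peak_shift(tr0), "identically zero")
})

test_that("spring production peak under midsummer photosynthesis or volatility", {
  sc_a <- get_scenario("fig5a_photo_peak", n_steps = 4000)
  tr_a <- pmp_solve(sc_a$rates, sc_a$params)
  expect_lt(tr_a$t_grid[which.max(tr_a$s)], 0.5)
  sc_b <- get_scenario("fig5b_volatility_drop", n_steps = 4000)
  tr_b <- pmp_solve(sc_b$rates, sc_b$params)
  expect_lt(tr_b$t_grid[which.max(tr_b$s)], 0.5)
  expect_equal(max(tr_b$s[tr_b$t_grid >= 0.5]), 0)  # silent after midsummer
})

test_that("elasticities of s(0) have the reported signs and magnitudes", {
  base <- list(p = 1, h = 2, b = 2, u = 1e-4, T = 1, s_max = 2)
  es <- lapply(c("p", "h", "b", "u", "T", "L0"), elasticity, base = base)
  names(es) <- c("p", "h", "b", "u", "T", "L0")
  vals <- vapply(es, `[[`, numeric(1), "elasticity")
  expect_true(all(vals[c("p", "h", "b", "T")] > 0))
  expect_lt(vals["u"], 0)
  expect_true(all(abs(vals["u"]) < abs(vals[c("p", "h", "b", "T")])))
  expect_equal(unname(vals["L0"]), 0, tolerance = 1e-10)
  # reproducible under halving of the step
  for (e in es[c("p", "h", "u")]) {
    expect_equal(e$elasticity, e$elasticity_half, tolerance = 1e-4)
  }
  # undefined when production never starts
  expect_error(elasticity("p", utils::modifyList(base, list(b = 0.5))),
               "undefined")
})

test_that("the costate equals future net production per leaf area", {
  tr <- solve_fig2(4000)
  dec <- marginal_value_decomposition(tr)
  expect_equal(dec$lam, dec$future_net_per_area, tolerance = 1e-5)
  n <- nrow(dec)
  expect_equal(dec$lam[n], 0)
  expect_equal(dec$future_net_per_area[n], 0)
  # zero-production phase: closed form p (1 - e^{-(u+h)(T-t)}) / (u+h)
  uh <- 2.0001
  zp <- dec$t > 0.67
  expect_equal(dec$future_net_per_area[zp],
               (1 - exp(-uh * (1 - dec$t[zp]))) / uh, tolerance = 1e-6)
  # tampered costate triggers the consistency error
  bad <- tr
  bad$lam <- bad$lam * 1.05
  expect_error(marginal_value_decomposition(bad), "identity violated")
  # strong-stress case: local min before midsummer, local max after
  sc4 <- fig4_case(4)
  dec4 <- marginal_value_decomposition(pmp_solve(sc4$rates, sc4$params))
  d <- diff(dec4$lam)
  i_min <- which(d[-1] > 0 & d[-length(d)] < 0) + 1L
  i_max <- which(d[-1] < 0 & d[-length(d)] > 0) + 1L
  expect_true(any(dec4$t[i_min] < 0.5))
  expect_true(any(dec4$t[i_max] > 0.5))
})
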