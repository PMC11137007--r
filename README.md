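# isosched

Optimal seasonal scheduling of isoprene production in tree leaves, solved by
Pontryagin's maximum principle, with an independent brute-force validation
oracle.

## The problem

Many deciduous trees emit isoprene, a highly volatile biogenic VOC that
protects leaves against heat stress — at a direct carbon cost. Over a growing
season `[0, T]` (leaf flush to leaf shedding), leaf area `L(t)` decays under a
background loss rate `u` and a seasonal hazard `h(t)` that isoprene production
`s(t)` suppresses:

    dL/dt = -( u + h(t) / (1 + b(t) s(t)) ) L,    L(0) = L0,

where `b(t)` is the effectiveness of isoprene. The tree chooses the production
schedule `0 <= s(t) <= s_max` (measured in carbon-cost units) maximising total
net photosynthesis

    phi = \int_0^T ( p(t) - s(t) ) L(t) dt.

The maximum principle yields a costate `lambda(t)` — the marginal value of
leaf area, equal to the future net production per unit area — integrated
backward from `lambda(T) = 0`:

    dlambda/dt = -(p - s) + lambda ( u + h / (1 + b s) ),

and the pointwise-optimal control is the feedback law

    s(t) = 0                                 if lambda b h <= 1
    s(t) = ( sqrt(lambda b h) - 1 ) / b      in between
    s(t) = s_max                             if lambda b h >= (1 + b s_max)^2.

Under constant rates the schedule has at most three phases —
max-rate, interior, zero — with the zero phase starting at

    t_s = T - ln( 1 / (1 - (u+h)/(p b h)) ) / (u+h),

and no production at all when `p b h <= u + h`. Seasonal rate profiles
(the exponentially modulated cosine `c exp[a1 +/- b1 cos(2 pi t/T)]`)
reshape the schedule: a midsummer hazard peak pulls production into summer
and — when total stress `H_total = \int h dt` is severe — pushes the
production peak *after* the hazard peak ("post-risk enhancement" of the
marginal value); midsummer peaks in photosynthesis or isoprene volatility
move production into spring.

## Worked example

```r
library(isosched)
rates  <- rate_set(p = rate_constant(1), h = rate_constant(2),
                   b_eff = rate_constant(2), u = 1e-4)
params <- season_params(T = 1, L0 = 1, s_max = 0.132)
traj   <- pmp_solve(rates, params)
traj
#> <iso_trajectory> 20001 grid points on [0, 1]
#>   phi = 0.443644, L(T)/L0 = 0.1660, max s = 0.132 (s_max = 0.132)
classify_phases(traj)
#> <iso_phases> max -> interior -> zero
#>   t_phase1_end = 0.2222918, t_s = 0.6534187
switching_time_constant(p = 1, h = 2, b = 2, u = 1e-4, T = 1)
#> [1] 0.6534187
```

The optimal schedule produces at the cap `s_max = 0.132` until `t = 0.222`,
then at a declining interior rate, and stops at `t_s = 0.653` — the numerical
phase boundary agrees with the closed form to 7 digits. The season's net
carbon gain is `phi = 0.4436`, versus `0.4323` with no production; 16.6% of
the leaf area survives to shedding.

The independent oracle confirms optimality by exact search over all
piecewise-constant schedules on 8 bins x 9 levels (the linear-in-`L` dynamics
let backward induction search the full 4.3e7-candidate space exactly):

```r
direct_optimize(rates, params, n_bins = 8, n_levels = 9)
#> <iso_oracle> exhaustive search over 8 bins x 9 levels (4.3e+07 candidates)
#>   phi_oracle = 0.44360439
#>   best schedule: 0.132 0.132 0.1155 0.0825 0.033 0 0 0
```

`phi_oracle <= phi`, and the best discrete schedule mirrors the
max -> interior -> zero shape. `dominance_test()` additionally checks the
solution against 500 random and locally perturbed schedules. Sensitivity of
the initial production rate to parameters:

```r
elasticity("p", list(p = 1, h = 2, b = 2, u = 1e-4, T = 1, s_max = 2))
#> <iso_elasticity> d ln s(0) / d ln p = 2.2166 (step 0.001, half-step 2.2166)
```

Elasticities with respect to `p`, `h`, `b`, `T` are positive; with respect to
`u`, negative and far smaller in magnitude.

Built-in seasonal scenarios (`get_scenario()`: `fig2_constant`,
`fig3_heat_peak`, `fig4_heat_peak_sweep`, `fig5a_photo_peak`,
`fig5b_volatility_drop`) and a CLI are included:

```sh
Rscript inst/cli/isosched.R scenario fig2_constant --out-dir out
Rscript inst/cli/isosched.R sweep --b1 1,2,4 --out-dir out
Rscript inst/cli/isosched.R validate --scenario fig2_constant --seed 1
```

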