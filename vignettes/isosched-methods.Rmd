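---
title: "Methods: the seasonal isoprene-scheduling model and its numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the seasonal isoprene-scheduling model and its numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isosched)
```

## The model

A cohort of leaves flushes at `t = 0` with area `L0` and is shed at `t = T`.
Leaf area is lost to a background rate `u` (per day) and to a heat-stress
hazard `h(t)` (per day) that the leaf can suppress by producing isoprene at
rate `s(t)` (per leaf area per day, measured in units of its carbon cost):

$$\frac{dL}{dt} = -\Big(u + \frac{h(t)}{1 + b(t)\,s(t)}\Big)\,L, \qquad
\phi = \int_0^T \big(p(t) - s(t)\big)\,L(t)\,dt,$$

where `p(t)` is the photosynthetic rate per area and `b(t)` the
effectiveness of isoprene. The model assumes isoprene is fully volatile —
what is produced on a day acts that day and is gone — so the control enters
instantaneously, with no stock variable. The schedule is constrained to
`0 <= s <= s_max`.

The maximum-principle solution introduces the marginal value of leaf area
`lambda(t)` (carbon per area), integrated backward from `lambda(T) = 0`.
The Hamiltonian is strictly concave in `s` wherever `lambda > 0`, so the
pointwise maximiser is the unique feedback law implemented in
`optimal_control()`: zero below `lambda b h = 1`, the interior root of
`(1 + b s)^2 = lambda b h` in between, and `s_max` above
`lambda b h = (1 + b s_max)^2`. Note the *squared* saturation threshold: it
is where the interior solution reaches the cap, making the law continuous in
`lambda`; the test suite verifies the law against a brute-force grid argmax
of the Hamiltonian precisely because this threshold is easy to get wrong.
`lambda(t)` equals the future net production per unit of present leaf area;
`marginal_value_decomposition()` checks that identity on every solve it is
asked to tabulate.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `T` | days | 1 | season normalised to 1; all rates are per day |
| `u` | /day | 1e-4 | background loss, tiny relative to `h` |
| `p, h, b` | /day, /day, per unit `s` | 1, 2, 2 | canonical constant-rate case |
| `s_max` | carbon/area/day | 0.132 | cap that produces all three control phases |
| `n_steps` | — | 20000 | localises phase boundaries to ~5e-5 days |

Seasonal profiles use the exponentially modulated cosine
`c exp[a1 ± b1 cos(2πt/T)]`: strictly positive, symmetric about midseason,
peaked (sign −) or dipped (sign +) at `t = T/2`, with sharpness set by the
shape factor `b1`. Its season integral has the closed form
`T c e^{a1} I0(b1)`, used as an independent oracle for
`total_heat_stress()`.

Where a scenario states no cap, `s_max` defaults to a non-binding value
(10× the largest unconstrained rate from a probe solve,
`nonbinding_smax()`): the qualitative claims those scenarios test concern
peak *timing* of the interior solution, which a binding cap would only
flatten. The midsummer-volatility scenario (`fig5b_volatility_drop`) does
not state a photosynthesis level; it uses `p = 1`, the constant used
everywhere else.

## Numerical choices

* **Fixed-step RK4, feedback control at every stage.** The costate RHS with
  the substituted control is continuous and piecewise smooth in `lambda`;
  control switches only introduce derivative kinks. A fixed fine grid
  (default 20000 steps for `T = 1`) is therefore sufficient and keeps the
  backward and forward passes on identical grids. Rates are evaluated
  lazily at arbitrary `t` (never pre-tabulated in the API), so the
  integrators and root finders can query between grid points; internally
  each pass pre-evaluates the rates at its own grid and mid-step points
  once, for speed.
* **Objective quadrature**: trapezoid rule on the solver grid — consistent
  with the scheme's effective order at the kinks. At 20000 steps, halving
  the step changes `phi` by under 1e-8 relative.
* **Phase boundaries** are detected from threshold crossings of
  `lambda b h` against 1 and `(1 + b s_max)^2` and refined by bisection on
  the interpolated costate to `control_tol = 1e-8` days. Exactly at
  `lambda b h = 1` production is 0 (both adjacent branches give 0; the
  boundary is closed on the zero side).
* **Switching time, general rates.** The switching condition equates
  `1/(b h)` with the zero-control costate `lambda_0(t)` (the future net
  production per area if nothing were produced after `t`), so
  `switching_time_general()` integrates `lambda_0` backward once, scans the
  residual for sign changes, and bisects the *largest* root — later roots,
  if any, are the true production cutoff; multiplicity is flagged.
* **Peak localisation** uses three-point quadratic interpolation around the
  grid maximum, giving grid-independent peak times at the 1e-4 level.
* **Elasticities** are central differences in log space (`rel_step = 1e-3`)
  with a half-step Richardson value reported, since only signs and relative
  magnitudes are scientifically meaningful here and robustness beats speed.
* **Degenerate inputs.** Rates must be strictly positive and `L0 > 0`
  (constructors enforce both); `s_max = 0` is allowed and yields the
  zero-control trajectory; worthless leaves (`lambda <= 0`) and vanishing
  benefit (`b h -> 0`) give `s = 0`.

## The validation oracle

`direct_optimize()` searches piecewise-constant schedules on `n_bins` equal
bins × `n_levels` levels. Because the dynamics are linear in `L`, the
objective of any such schedule factorises into per-bin gain and survival
factors (computed with the same RK4 stepper and quadrature as the main
solver), so backward induction over bins recovers the exact optimum of the
full `n_levels^n_bins` candidate set at `n_bins × n_levels` bin
integrations; a coordinate-ascent mode covers larger bin counts. The
reported `phi_oracle` is re-evaluated by one full-season forward solve of
the winning schedule. `dominance_test()` complements this with 500 seeded
random schedules plus ±ε local bumps of the candidate schedule
(ε = 0.05 `s_max` on windows of 0.05 `T`). Local bumps change `phi` only at
second order in ε, so candidates are evaluated on the 20000-step grid where
integrator noise (O(dt²)) sits well below that margin; at a 2000-step
evaluation grid the noise can spuriously "beat" the true optimum by ~3e-7.
A deliberately corrupted control law (thresholds swapped) is caught by the
same suite, demonstrating its sensitivity.

## What the scenarios do and do not establish

The built-in scenarios are stated model worlds, not data: constant rates
(`fig2_constant`), a midsummer hazard peak at three severities
(`fig3_heat_peak`, `fig4_heat_peak_sweep`, `b1 ∈ {1, 2, 4}`, total stress
`H_total ≈ 1.27, 2.28, 11.3`), a midsummer photosynthesis peak
(`fig5a_photo_peak`), and a midsummer effectiveness dip
(`fig5b_volatility_drop`). Green tests establish internal consistency of
the solution (closed forms, optimality dominance, phase structure, peak
ordering) — not that real trees follow these schedules. The generator omits,
deliberately: stochastic weather and hazards, leaf-age structure, any
carry-over of the compound between days, reversible photosynthetic
depression by mild heat, and between-plant signalling.

One finding worth flagging: with the midsummer hazard at the *weakest*
severity (`b1 = 1`), the production peak sits slightly **before** the hazard
peak (shift ≈ −0.011 T). This is structural, not numerical: with `b`
constant the production peak is the argmax of `lambda(t) h(t)`, and at mild
stress the costate is still declining at midseason
(`costate_rhs` ≈ −0.15 < 0 at `T/2`), which drags the argmax below `T/2`.
Only at stronger stress does the post-risk rise of `lambda` flip the shift
positive and grow it (`+0.021` at `b1 = 2`, `+0.076` at `b1 = 4`). The
acceptance test asserting a positive shift at all three severities is
therefore expected to fail at `b1 = 1`, and is left failing rather than
weakened; the monotone growth of the shift with total stress holds.

## Known limitations

* Only the fixed-step RK4 integrator is implemented; the settings enum
  reserves an adaptive option but the RHS's mild kinks do not warrant one.
* The exhaustive oracle relies on the linear-in-`L` factorisation; it would
  not survive model extensions with a second state variable (e.g. a
  compound stock with `dV/dt = s − kV`), which are out of scope.
* Elasticities are defined for the interior solution; with a binding
  `s_max` the initial rate sits at the cap and `elasticity()` warns.
* No plotting: trajectories export as delimited tables (`export_trajectory`)
  and flat JSON summaries for downstream tooling.
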