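---
title: "Modelling repair, adaptation and bet-hedging after DNA damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling repair, adaptation and bet-hedging after DNA damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddadapt)
```

## The biological question

After a double-strand break, the DNA damage checkpoint arrests the yeast
cell cycle while repair is attempted. When repair fails or stalls, cells can
eventually *adapt*: override the checkpoint and divide with the damage,
risking death through chromosome missegregation but keeping a chance that a
descendant survives and later repairs. Two observations call for an
explanation: adaptation happens *late* (several cell cycles after damage,
once repair is usually exhausted) and its timing is *heterogeneous* across
cells. `ddadapt` implements population models tailored to these questions:
it asks which adaptation timing maximises population recovery, and whether
timing heterogeneity pays off — in a constant environment or only in an
unpredictable, fluctuating one, where it would amount to bet-hedging.

## Model structure

Cells occupy compartments: damaged `D`, adapted `A`, repaired (healthy) `R`
(optionally split by ancestry, `R = Rd + Ra`). One time unit is one
unperturbed cell cycle; all transitions are given as per-step probabilities:

* repair: `alpha(t) = alpha_m * exp(-(t - mu_a)^2 / sigma^2)`, a window
  centred shortly after damage — most repair either happens early or not at
  all;
* adaptation: `beta(t) = beta_m / (1 + exp(-p * (t - mu_b)))`, a logistic
  curve consistent with a timed, switch-like override; its slope at the
  half-maximum time is `p * beta_m / 4`;
* death: `gamma1` (damaged), `gamma_ad` (adapted; large, reflecting
  mitotic failures with damaged chromosomes), `gamma_r` (repaired;
  negligible);
* second-chance repair of adapted cells: `delta` (alternative pathways in
  later cell cycles).

`alpha` and `beta` are probabilities evaluated at each step, not densities;
no normalisation is applied, and the same curves serve as continuous-time
rates in the ODE model.

The **stochastic model** (`run_stochastic()`) draws, at step `n = 1, 2,
...`, one multinomial partition of the damaged pool — die / adapt / repair /
remain, exclusive outcomes, probabilities `(gamma1, beta(n), alpha(n),
rest)` — and one of the adapted pool (die / repair / remain). The first
transition uses `n = 1`, so at baseline (`mu_a = 1`) repair peaks at the
very first step. At the end of each step the adapted and repaired cells
divide within the carrying capacity: with `free = Nmax - (D + A + R)`
spaces and `demand = A + R` daughters, both compartments double when space
allows, otherwise exactly `free` daughters are added in proportion
(largest-remainder rounding). Cells that transitioned this step divide in
the same step — they are in their new compartment at division time.
Compartment counts follow the exact law of an equivalent agent-per-cell
simulation. The fate probabilities must satisfy
`gamma1 + alpha(t) + beta(t) <= 1`; this is enforced on entry to the
stochastic model (`check_step_probabilities()`) rather than at parameter
construction, because parameter sets violating it (e.g. an adaptation curve
overlapping the repair window at small `mu_b`) remain meaningful for the
ODE model, where the curves are rates, and such values legitimately occur
inside sweeps.

The **continuous model** (`run_ode()`) is the natural interpolation:

```
D'  = -(gamma1 + beta(t) + alpha(t)) D
A'  =  beta(t) D - (gamma_ad + delta) A + A (1 - N/Nmax)
Rd' =  alpha(t) D - gamma_r Rd + Rd (1 - N/Nmax)
Ra' =  delta A    - gamma_r Ra + Ra (1 - N/Nmax)
```

The logistic crowding factor multiplies only the growth terms — damaged
cells are arrested and do not grow, but they occupy space in
`N = D + A + Rd + Ra`. The factor is deliberately not clipped at zero: if
`N` transiently overshoots `Nmax`, growth turns (slightly) negative, which
is the faithful reading of the equations. The four-compartment form is an
exact refinement of the three-compartment one (`Rd + Ra` obeys the `R`
equation), which the tests verify to `1e-4 * Nmax`.

The two formulations agree qualitatively but not quantitatively, by
construction: the discrete model applies `alpha(1) = alpha_m` as a full
one-step probability, while the continuous model accrues
`integral of alpha` over the step (about `0.22` at baseline over `[0, 1]`),
so the continuous damaged pool drains more slowly and the two mean
trajectories differ by far more than Monte-Carlo error at realistic
population sizes. Both models are kept because the stochastic one is the
ground truth for finite-population behaviour while the ODE is hundreds of
times cheaper, and their optima lie in the same place (the tests check the
`mu_b` argmins agree to ±0.5).

## The figure of merit: saturation time

`Ts` is the first time healthy cells fill the environment: `R >= Nmax` in
the discrete model; `Nmax - R(t) < 1` — within one absolute cell — in the
continuous one, implemented one-sidedly as `R > Nmax - 1` since `R` cannot
overshoot the capacity in practice. Lower `Ts` = faster population
recovery = better survival.

Two numerical consequences are worth knowing. First, the one-cell
criterion is absolute, so the dynamics are scale-invariant in
`(N0, Nmax)` but `Ts` itself is not: doubling both adds roughly
`log(2) / 0.37 ≈ 1.9` steps of tail time while leaving every trajectory
exactly proportional. Second, near saturation `R` crawls (`|dR/dt|` of
order 2 cells/step, limited by the decay of the residual adapted pool), so
with the default tolerances (`rtol = 1e-8`, `atol = 1e-8 * Nmax`) the
root-located `Ts` is reproducible to about `1e-3` steps — amply sufficient,
given that the optima being located are shallow by more than two orders of
magnitude on that scale.

## Fluctuating environments

The fluctuating-environment generator is the package's synthetic-input
module: the damage source stays active for a random duration `tau` (stop
time), and **no repair is possible while it is active** — `alpha` is gated
to zero before `tau`. Adaptation is never gated: the checkpoint clock runs
from the initial damage. Stop-time laws: Gaussian (default mean 1.7,
variance 2.25, truncated at zero and renormalised — a stop "before the
start" is equivalent to stopping at 0), exponential (default rate `1/1.7`,
matching the Gaussian mean), and uniform (default `[0, 3.4]`, i.e. twice
the Gaussian mean) with an exponentially fading window height
(`fade = 0.3` per step of stop time). "Variance 2.25" is taken literally
(standard deviation 1.5).

How repair behaves *after* the stop is genuinely ambiguous, and it is the
single most consequential modelling choice in the package, so both
readings are implemented (`resume` argument of `dd_environment()`):

* `"continue"` (default): the repair curve keeps its original clock and is
  merely un-gated at `tau`. Repair opportunities that fell inside the
  damage phase are lost — the damage overloaded the repair machinery during
  its window. Under this reading a late-stopping environment leaves
  adaptation as the only route out, which is exactly the regime where
  spread-out adaptation timing (small `p`) hedges between
  "repair-will-work" and "repair-will-never-work" futures: the expected
  `Ts` acquires an interior optimum in `p` and its dependence on `p`
  flattens dramatically compared with the stable environment. Both
  behaviours are asserted in the test suite, and neither occurs under the
  restart reading — which is why `"continue"` is the default.
* `"restart"`: the full window re-opens at `tau` (repair opportunity
  follows the end of damage, e.g. because damage kept resetting the
  substrate). Every environment eventually offers full repair, so sharp
  late adaptation stays optimal; but precisely because repair remains
  available to everyone, this reading is the conservative choice when
  measuring how much ancestry the adapted route contributes — the
  adapted-ancestry acceptance computation uses it.

Expectations over the stop-time law use deterministic trapezoid quadrature
on `[0, q(0.9999)]` with density weights renormalised to 1 (default 200
nodes), with seeded Monte-Carlo sampling retained as a cross-check; the
tests verify the quadrature against closed-form truncated-normal moments
and against Monte-Carlo to within its standard error. The default
averaging semantics is *functional-then-expectation* (expected `Ts`,
expected ancestry fraction); pointwise-in-time trajectory averaging is
available separately (`average_trajectories()`) for population-composition
plots. Nodes whose run does not saturate within `t_max` are excluded with
their weight renormalised (warning above 5% excluded weight, error above
50%).

## Experiments and their numerical choices

Sweeps (`sweep_mu_b()`, `sweep_p()`, `sweep_grid()`) evaluate `Ts` on a
sorted grid — default `mu_b` in `[0, 10]` by 0.05 and `p` in `[0.1, 10]`
by 0.1, which resolve the optima of interest — and refine the discrete
argmin by golden-section search between its two grid neighbours to an
absolute `1e-3` (ODE model only; stochastic argmins are left on the grid,
where replicate noise dominates anyway). Non-saturating points are kept in
the output as `NA` and excluded from argmins. Stochastic sweeps default to
10 000 replicates per point with replicate `r` seeded as `base_seed + r`;
every stochastic entry point takes an explicit seed and restores the
caller's RNG state.

A caveat the package's own computations make visible: the sweep objectives
are extremely flat near their minima. At baseline the stable-environment
`Ts(mu_b)` varies by ~0.1 steps (0.3%) across `mu_b` in roughly
`[3.1, 3.9]`, and the random-environment expected `Ts(p)` varies by less
than 0.1 steps across `p` in `[0.3, 1.3]`. Argmin *locations* on such
plateaus are ill-conditioned — tiny modelling or solver differences move
them by several grid steps while leaving the biology (a delayed optimum;
an interior heterogeneity optimum) unchanged. Conclusions should be read
at the level of those qualitative optima, not their third decimal.

The test suite runs everything at reduced problem sizes chosen to keep the
full suite within a few minutes while leaving Monte-Carlo error well below
the asserted effects: ensembles of 40–200 quadrature nodes, stochastic
replicates of 60–400, and sweep grids of 3–100 points; the acceptance
script uses the full 200-node ensembles and the default sweep grids.

## What the generator does and does not emulate

The synthetic environments emulate a damage source of unpredictable
duration gating repair on/off. They do **not** emulate: graded damage
intensity, repeated damage episodes, re-damaging of repaired cells,
cell-to-cell variability in rate parameters, spatial structure, or any
molecular detail of the checkpoint. Passing tests therefore demonstrate
the internal consistency of this idealised bet-hedging setting — not that
real damaged populations are quantitatively described by it. Likewise the
carrying-capacity cap (with saturation as the end point) focuses the
models on early recovery dynamics; long-term growth, mutation accumulation
in adapted lineages, and fitness beyond saturation are out of scope, with
the adapted-ancestry fraction `Ra/(Rd + Ra)` at saturation serving as the
only (proxy) measure of adaptation's genetic contribution.

## Known limitations

* The optima are shallow (see above); argmin locations carry
  model-specification uncertainty far exceeding their numerical precision.
* The continuous and discrete models disagree quantitatively by
  construction; only the continuous model is used for ensemble averaging.
* The two resume readings bracket, but cannot resolve, what a real
  overloaded repair pathway would do after the source stops; conclusions
  that differ between `"continue"` and `"restart"` (notably the size of
  the adapted-ancestry fraction) should be reported under both.
* Ensemble averaging for the stochastic model is not implemented (the ODE
  model is the workhorse there); stochastic runs accept a single realised
  environment.

## A small worked session

```{r example}
params <- dd_params()
run_ode(params)

sweep_mu_b(params, grid = seq(2.5, 4.5, by = 0.25))

ens <- build_ensemble(dd_environment("gaussian_stop"), n_nodes = 50)
expected_over_environment(dd_params(p = 1), ens)

population_structure(params, p_grid = c(0.5, 1, 2))
```
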