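---
title: "A principal–agent model of reproductive skew: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A principal–agent model of reproductive skew: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reproskew)
```

## The model and its assumptions

Two males share a territory. The dominant (Alpha) controls the fraction
`c ∈ [0, 1]` of the subordinate's (Beta's) brood that Beta sires — in
employment terms, Alpha sets Beta's wage in the currency of paternity. Beta
then chooses a feeding effort `f ∈ [0, 1]` (fraction of the biological
maximum) for his mate's brood. Feeding is dangerous: effort `f` carries a
mortality probability `p f²`, and death forfeits the expected future
lifetime fitness `w̄`. Beta's per-period fitness is therefore

$$ w = c f - \bar{w} p f^2, $$

with lifetime version `w_L = c f + (1 − p f²) w̄ = w + w̄`. The female is
not a strategic player: her mating pattern is summarized by `c` being under
Alpha's control. Alpha additionally rears his own, genetically exclusive
brood with effort `F` and payoff `W_α = F − w̄ p F²`.

Three assumptions matter for interpretation. First, the paternity benefit
is linear in effort (`c f`); diminishing returns would change magnitudes
but not the qualitative logic, and are not modelled. Second, both males
face the same `w̄` in their mortality terms. Third, Alpha moves first and
Beta best-responds — the equilibrium is the subgame-perfect outcome of a
sequential game, which is also a Nash equilibrium of the simultaneous
game (verified by `verify_nash()`).

Maximizing `w` in `f` gives Beta's best response (incentive-compatibility
constraint) `f*(c) = c/(2 w̄ p)`; maximizing Alpha's brood-share payoff
`W_β = (1 − c) f*(c)` gives `c* = 1/2`. The resulting fitnesses are in the
ratio `W_β*/w* = 2` and the two-male Gini is `5/7`. Joint fitness is
increasing in `c`, maximal at full concession `c = 1` where the two
fitnesses are equal — the equilibrium is evolutionarily stable but
Pareto-inefficient.

## Parameters

| Parameter | Meaning | Units | Constraint | Notes |
|---|---|---|---|---|
| `wbar` | expected future lifetime fitness | fitness | `> 0` | enters only via `wbar * p` |
| `p` | mortality cost coefficient | — | `(0, 1]` | `p f²` must be a probability on `f ∈ [0, 1]` |
| `z` | subordinate's outside option | fitness/period | `≥ 0` | drives the regime |
| `Z` | dominant's outside option | fitness/period | `≥ 0` | default 0: his fallback is breeding alone, already counted in `W_α` |

Every equilibrium quantity depends on `wbar` and `p` only through their
product, so `wbar = p = 1` is the canonical scale; the package's tests
assert this scale property explicitly.

## Constraint regimes and boundary clamping

The subordinate's participation constraint `w ≥ z` defines a minimum
acceptable share `c̄ = √(4 w̄ p z)` and three regimes: incentive-binding
(`z ≤ 1/(16 w̄ p)`), participation-binding (`c* = c̄`, the subordinate
earning exactly `z`), and no employment (`z ≥ 1/(4 w̄ p)`). Ties at the
thresholds follow those inequality directions. The dominant's own
participation (`W ≥ Z`) is checked afterwards and can force no employment
for a user-supplied `Z`.

The closed forms assume interior optima. When `w̄ p < 1/2` the analytic
best responses would exceed the feasible maximum, so `beta_best_response()`
clamps at 1 (flagging `clamped`), `unconstrained_equilibrium()` maximizes
the dominant's piecewise objective numerically with `stats::optimize()`
(the objective is unimodal: a concave arc followed by a decreasing linear
branch), and results carry `boundary_clamped = TRUE`. The regime
thresholds are extended piecewise for these cases — `z_low = w̄p` when
`w̄p < 1/4` (the unconstrained optimum sits at the clamp kink `c = 2 w̄p`),
`z_high = 1 − w̄p` when `w̄p < 1/2` (the clamped payoff at `c = 1`) — which
reduce exactly to the printed forms at `w̄p = 1/2` and `1/4`. The solver
itself decides the regime operationally, comparing `c̄` with the (possibly
numeric) unconstrained optimum under a `1e-9` tolerance that absorbs
optimizer jitter, so classification and solution never disagree.

Off-optimum per-period fitness may be negative and is returned as-is;
fitness functions are mathematical objects. Only the evolutionary
simulator floors fitness at 0, because sampling weights must be
non-negative — a selection-model choice, not a property of the fitness
function.

## The Gini convention

For two fitnesses the package uses the small-sample-corrected Gini
`|a − b| / (a + b)` (correction factor `n/(n − 1) = 2`): this is the
convention under which the equilibrium fitnesses `1/16` and `3/8` give
`5/7 ≈ 0.71`; the uncorrected estimator would give half that, and is
available via `corrected = FALSE`. `gini_general()` implements the
pairwise mean-absolute-difference form for arbitrary vectors (computed via
the sorted-rank identity, tested against the brute-force pairwise sum) and
reduces exactly to the two-sample form at `n = 2` with correction.
Population summaries in the simulator use the uncorrected estimator, the
usual choice for populations rather than pairs.

## Verification oracles

The closed forms are never trusted in isolation. `grid_best_response()`
re-derives the best response by grid search (1001 points, three local
zoom rounds, ties toward smaller effort); `verify_nash()` scans unilateral
deviations on each strategy axis, with Beta re-best-responding when Alpha
deviates in `c` (respecting the sequential structure); `invasion_fitness()`
compares a rare mutant dominant against the resident, frequency effects
being absent because fitness accrues within a territory;
`find_pareto_improvement()` searches the `(c, f)` grid for allocations
raising both fitnesses strictly, returning the improvement maximizing the
smaller gain. Default deviation tolerance is `1e-7` on fitness; all model
quantities are O(1) at the canonical scale, and the test suite uses `1e-9`
absolute tolerance for closed-form-vs-numeric agreement.

## Evolutionary dynamics

The game's stability claim is made dynamic in two ways.

**Adaptive dynamics.** `adaptive_dynamics()` integrates
`dc/dt = (1 − 2c)/(2 w̄ p)` (the selection gradient on the dominant's
payoff) by the Euler method, clamped to `[0, 1]`. The flow has the closed
form `1/2 + (c₀ − 1/2) e^{−t/(w̄ p)}`, against which the integration is
tested.

**Wright–Fisher simulation.** `simulate_evolution()` evolves a population
of `N` dominant territories with a heritable share trait `c_i`. Each
generation, every dominant interacts with a subordinate feeding at
`f*(c_i)` — or, when coevolving, at `min(a_j c_i, 1)` for a randomly paired
subordinate lineage with heritable reaction-norm slope `a_j`, the linear
norm being exact because the analytic best response is linear in `c`.
Per-period fitnesses (dominant `W_β + W_α`, subordinate `w`), floored at 0,
are the weights for fitness-proportional resampling; offspring mutate with
probability `mutation_rate` (default 0.05) by a zero-mean Gaussian of sd
`mutation_sd` (default 0.02), reflected into the trait range (`[0, 1]` for
`c`, `[0, 1/(w̄ p)]` for `a`). A seed is mandatory; identical seed and
configuration give bitwise-identical trajectories. This is the minimal
standard population process that makes "invasion by mutation or migration"
operational; it adds no spatial, age or genetic structure, and none is
claimed.

A point worth understanding before interpreting short runs: selection on
the share trait is weak. By the Price equation the per-generation change
of the mean share is roughly `Var(c) · (1 − 2c̄) / (2 W̄)`, and the mean
total fitness `W̄` includes the constant own-brood term `W_α = 1/(4 w̄ p)`,
which dilutes relative fitness differences. At the default mutation scales
the standing variance settles near `sd(c) ≈ 0.03`, giving an equilibration
time constant of several hundred generations. Runs of ~300 generations
started far from the equilibrium therefore still sit visibly below `1/2`,
while the long-run mean recovers the attractor; the package's convergence
test accordingly uses 1200 generations (N = 200, 5 seeds, long-run mean
within ±0.05 of 1/2). The subordinate's reaction-norm slope, by contrast,
experiences much stronger relative selection (no constant term in his
fitness) and converges within ~300 generations. These problem sizes — and
the oracle grids of 101–2001 points — are the package's chosen test
scales.

## What the simulator does and does not emulate

The simulator emulates trait evolution under the model's own fitness
functions: it can show that the analytic equilibrium is an attractor of a
standard mutation–selection process, and how fast. It does not emulate
real cooperative-breeder data: broods are not discrete, there is no
female strategy, no relatedness, no territory turnover or inheritance, and
outside options are exogenous constants. Passing tests therefore validate
the mathematics and the dynamics of this model, not the model's fit to any
field system.

## Known limitations

* Interior closed forms require `w̄ p ≥ 1/2`; below that, results are
  numeric and flagged, and the printed threshold formulas are replaced by
  their piecewise extensions.
* The participation analysis treats `z` and `Z` as constants; nothing
  feeds back from population state to outside options.
* The Gini convention was chosen to be the standard corrected two-sample
  estimator; users comparing against uncorrected published values should
  set `corrected = FALSE`.
* Short stochastic runs underestimate the equilibrium share for the reason
  quantified above; use the long-run mean, or adaptive dynamics, when the
  attractor itself is the question.
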