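# reproskew

Reproductive skew — the unevenness with which breeding is shared among the
members of a social group — is a central quantity in the study of
cooperatively breeding animals. `reproskew` implements a two-male
principal–agent game of skew between a territory-holding dominant ("Alpha")
and a subordinate helper ("Beta"): the dominant grants the helper access to
the territory and controls the fraction `c` of the helper's own brood that
the helper actually sires (the "wage"), while the helper chooses how much
food `f` to deliver to that brood, at a quadratic mortality cost. The
package is aimed at behavioural ecologists and evolutionary game theorists
who want the model's equilibria, comparative statics and evolutionary
dynamics as tested, scriptable code.

## The model

Both efforts are fractions of their biological maxima. Feeding at effort
`f` kills the feeder with probability `p f²`, forfeiting an expected future
lifetime fitness `w̄`. The subordinate's per-period fitness is

    w = c f − w̄ p f²

so his best response (the incentive-compatibility constraint) is
`f*(c) = c / (2 w̄ p)`. The dominant, moving first, keeps the share
`(1 − c)` of the helper's surviving brood, `W_β = (1 − c) f*(c)`, and feeds
his own brood optimally at `F* = 1 / (2 w̄ p)` for `W_α = 1 / (4 w̄ p)`.
Maximizing `W_β` gives the equilibrium wage `c* = 1/2`, hence

    f* = 1/(4 w̄ p),  w* = 1/(16 w̄ p),  W_β* = 1/(8 w̄ p),  W* = 3/(8 w̄ p),

a fitness Gini between the two males of 5/7 ≈ 0.71, a Nash equilibrium that
is evolutionarily stable yet Pareto-inefficient: joint fitness would be
maximized (and skew would vanish) at full concession `c = 1`. Outside
options bound the bargain: the helper's reservation fitness `z` raises the
minimum acceptable wage to `c̄ = √(4 w̄ p z)`, so the equilibrium passes
from incentive-binding (`z ≤ 1/(16 w̄ p)`, `c* = 1/2`, Gini 0.71) through
participation-binding (`c* = c̄`, Gini falling) to no employment at all
(`z ≥ 1/(4 w̄ p)`).

Everything above is implemented in closed form, cross-checked by
brute-force grid oracles (`grid_best_response()`, `verify_nash()`,
`invasion_fitness()`, `find_pareto_improvement()`), and confirmed
dynamically by deterministic adaptive dynamics and a Wright–Fisher
mutation–selection simulation, optionally coevolving the helper's feeding
reaction norm `f = min(a c, 1)` (target slope `a* = 1/(2 w̄ p)`).

## Worked example

```r
library(reproskew)

pars <- skew_params(wbar = 1, p = 1, z = 0.16)  # w̄p = 1, helper can earn 0.16 elsewhere
constrained_equilibrium(pars)
#> <skew_equilibrium>  regime: participation_binding
#>   c* = 0.8  f* = 0.4  F* = 0.5
#>   w = 0.16  W_beta = 0.08  W_alpha = 0.25  W_total = 0.33
#>   joint = 0.49  Gini = 0.346939
```

The helper's outside option (0.16) exceeds the incentive-binding threshold
1/16, so his participation constraint binds: the dominant must concede
`c̄ = √(4 · 0.16) = 0.8` of the helper's brood, the helper feeds at
`f*(0.8) = 0.4` and earns exactly his outside option, and skew drops from
0.71 to 0.35. Sweeps (`run_sweep()`), tidy one-row summaries
(`tidy()`/`glance()`), plots (`autoplot()`,
`plot_skew_vs_outside_option()`) and a CLI (`inst/cli/reproskew.R`, with
`solve`, `sweep`, `simulate`, `verify` and `fixtures` subcommands) build on
the same solvers.

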