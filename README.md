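# cprgame

Tools for studying the tragedy of the commons as a *learning* problem.
`cprgame` implements a common-pool resource game in which a group of `n`
harvesters repeatedly chooses efforts against a renewable stock, together
with (i) a closed-form bioeconomic analysis of the action space and (ii)
decentralised tabular Q-learning agents whose reward trades an individual
profit motive against a collective sustainability norm. It is aimed at
researchers in ecological economics, social dilemmas and multi-agent
reinforcement learning who want a small, fully reproducible sandbox where
analytical geometry and learned behaviour can be compared directly.

## The model

The stock `N` follows

```
N_t = N_{t-1} + G(N_{t-1}) - H(X_t, N_{t-1})
G(N) = r_g N (1 - N / N_max)              (logistic regrowth)
H(X, N) = beta X^alpha N^(1 - alpha)      (Cobb-Douglas production)
```

where `X = sum_i x_i` is the group's cumulative effort, constrained to
`[X_min, X_max]`. Payoffs share the harvest by effort at linear cost,
`pi_i = (x_i / X) H - c x_i`, and assets accumulate one round in arrears.
Two effort boundaries organise the action space: the sustainable bound
(net growth `G - H >= 0`) and the profitable bound (total profit
`H - c X >= 0`); their interplay defines the equilibria `E1`, `E2`
(sustainability limits), `E_profitable` and `E_optimal` (the stock level
with the widest interval of efforts that are both sustainable and
profitable). Learning agents receive the trend reward
`R = w * sign(pi_i) + (1 - w) * sign(G - H)`.

## Worked example

```r
library(cprgame)

# 1. What does the action space offer?
glance(yield_analysis())
#> # A tibble: 1 x 7
#>   E1_sustainable E2_sustainable E_profitable E_optimal X_e_lower X_e_upper viable_fraction
#>            63.8           563.         141.      291.       100      206.          0.0613
```

Under the reference parameters (`cprg_params()`: `N_max = 1000`,
`r_g = 0.5`, `alpha = 0.35`, `beta = 0.4`, `X_min = 100`, `X_max = 500`,
`c = 0.5`), harvesting is sustainable only while the stock sits between
about 64 and 563 units, turns a profit only above about 141, and the
safest operating point is near 291, where any cumulative effort between
100 and about 206 keeps both conditions. Only ~6% of the feasible
effort-by-stock rectangle is viable — the game is built to be hard.

```r
# 2. Can profit-aware learners find that region?
sim <- run_cprg(rounds = 2000, replicates = 5, n_agents = 10, base_seed = 42)
glance(sim, late_window = 500)
#> # A tibble: 1 x 5
#>   replicates median_late_N mean_late_X median_final_assets depleted_fraction
#>            5          452.        152.              10534.                 0
```

After a learning phase, ten agents weighting profit and sustainability
equally hold the stock around 452 — inside the viable band — with a mean
cumulative effort of ~152 and median per-agent assets above ten times the
initial endowment of 1000: the group has learnt restraint without giving
up profit. `autoplot(sim)` shows the trajectories, `sweep_group_size()`
and `sweep_cost_weight()` run the group-size and cost/weight experiments,
and `write_outputs()` exports tidy CSVs. A thin command-line front end
with the same capabilities lives at `inst/cli/cprg`
(`analyze | simulate | sweep-n | grid-cw | fixture`).

See the methods vignette (`vignettes/cprg-methods.Rmd`) for the model's
assumptions, the learner design and its rationale, and known limitations.

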