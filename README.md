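# exploregen

Tools for studying the exploration-exploitation trade-off in
intergenerational technology transmission: how much of a fixed time budget
a rational individual should spend *exploring* better designs of a
culturally transmitted technology versus *exploiting* the current design
for immediate pay-off, when the final design is handed to a successor.
The package is aimed at researchers in cultural evolution and social
learning who want a tested, scriptable implementation of the three layers
of this framework: formal model, agent-based simulation and
behavioural-statistics pipeline.

## What it implements

**Analytic allocation game.** Two players in sequence, each with time
budget `T` and a learning curve `f(t)` (efficiency after `t` time of
exploration; `f >= 0`, `f' > 0`, `log f` concave). The first player's
optimal switching time solves the marginal-balance condition

```
f'(t_p) / f(t_p) = 1 / (T - t_p)
```

In the *repaid* condition (the first player receives a bonus equal to the
second player's earnings) the problem is the same with horizon `2T`, so the
optimal exploration time can only grow. `solve_allocation()` solves both
conditions by bracketed bisection; `grid_oracle()` verifies by brute force.

**Win-stay/lose-shift simulation.** Agents on a virtual-arrowhead task
(three integer attributes, unimodal quadratic expected score, `N(0, 5^2)`
display noise, 50 trials, step size `L = 5`) alternate exploitation and
exploration for `tau` explorations and then exploit. From an ensemble
estimate of the discrete learning curve `g(tau)`,

```
W_u(tau) = sum_{k < tau} g(k) + (T - 2 tau) g(tau)      # unrepaid/asocial
W_r(tau) = sum_{k < tau} g(k) + (2T - 2 tau) g(tau)     # repaid
```

`optimal_tau()` locates the pay-off-maximizing exploration count. On the
package's calibrated default landscape the optima are `tau* = 12`
(unrepaid/asocial) and `tau* = 22` (repaid).

**Statistics pipeline.** Per-trial logs (CSV, one row per
participant-trial) are analyzed with Welch t-tests at the
Bonferroni-adjusted threshold `alpha = 0.025`, Cohen's d (pooled SD),
final-design efficiencies and the calorie-to-yen payment rule.
`synth_participants()` generates fully consistent synthetic cohorts
(per-condition exploration-count distributions, trajectories simulated by
the WSLS agent) so the entire pipeline runs without human data.

## Worked example

```r
library(exploregen)

# analytic: linear learning curve f(t) = 1 + 2t, horizon T = 1
lc <- learning_curve(function(t) 1 + 2 * t, T = 1)
solve_allocation(lc, "unrepaid")
#> Allocation (unrepaid): tp* = 0.25, ts* = 0, W_p = 1.125, W_s = 1.5
solve_allocation(lc, "repaid")
#> Allocation (repaid): tp* = 0.75, ts* = 0, W_p = 3.125, W_s = 2.5

# simulation: learning curve from a 10,000-agent ensemble, then optima
g <- estimate_learning_curve(default_landscape(), n_agents = 10000, seed = 1)
optimal_tau(g, condition = "unrepaid")
#> Optimal exploration count (unrepaid): tau* = 12 (per-trial pay-off 448.3)
optimal_tau(g, condition = "repaid")
#> Optimal exploration count (repaid): tau* = 22 (per-trial pay-off 1218.7)

# statistics: synthetic cohorts through the planned contrasts
logs <- synth_participants(default_synth_config(n = 20), seed = 42)
analyze_exploration(logs)[["repaid:asocial"]]
#> M1 = 25.80 (SD 6.40, n 20) vs M2 = 20.40 (SD 3.99, n 20)
#> Welch t(31.85) = 3.203, p = 0.003081, d = 1.01 (alpha = 0.025: significant)
```

The first player of a linear curve explores a quarter of its time when
unrepaid and three quarters when repaid; the simulated agents stop
alternating at trial 24 (unrepaid) versus trial 44 (repaid); and the
synthetic repaid cohort's extra exploration is detected at the corrected
threshold while the unrepaid-vs-asocial contrast is not (run it to see the
second comparison).

A thin command-line front end over the same functions ships in
`inst/cli/exploregen` (subcommands `solve`, `learning-curve`,
`optimal-tau`, `chain`, `synth`, `analyze`).

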