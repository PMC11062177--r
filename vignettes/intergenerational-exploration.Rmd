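---
title: "Models and methods: exploration-exploitation trade-offs across generations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: exploration-exploitation trade-offs across generations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exploregen)
```

## The scientific question

When a technology is handed down from one generation to the next, the
predecessor faces a trade-off: time spent *exploring* better designs
improves the technology that the successor inherits, but costs the
predecessor opportunities to *exploit* the current design for immediate
returns. `exploregen` implements three coupled layers for studying this
trade-off:

1. an **analytic model** — a continuous two-player sequential game with an
   optimal switching-time solution;
2. an **agent-based simulation** — win-stay/lose-shift (WSLS) agents on a
   virtual-arrowhead task, used to locate the optimal number of discrete
   exploration trials per incentive condition; and
3. a **statistics pipeline** — the Welch-t/Cohen's-d analysis applied to
   per-trial behavioural logs, with a synthetic-participant generator so
   the pipeline is fully testable without human data.

Two incentive schemes are contrasted throughout. In the **unrepaid**
condition the first player earns only its own score even though its final
design is transmitted; in the **repaid** condition it additionally receives
a bonus equal to the successor's earnings. An **asocial** control (no
transmission) has the same pay-off structure as the unrepaid condition for
the first player, and hence the same optimum.

## The continuous allocation game

Each player has a time budget $T$. Efficiency (pay-off per unit time of
exploitation) follows a learning curve $f(t)$ of cumulative exploration
time $t$, with $f(t) \ge 0$, $f'(t) > 0$, and $\log f$ concave on
$[0, 2T]$. Because $f$ is deterministic and increasing, rational players
front-load exploration: the first player explores until a switching time
$t_p$ and then exploits, earning $W_{p,u} = (T - t_p)\, f(t_p)$; the second
player continues from the inherited level, earning
$W_s = (T - t_s)\, f(t_p + t_s)$. The repaid first player maximizes
$W_{p,r} = W_{p,u} + W_s$.

An interior optimum balances the marginal benefit of exploration against
its marginal cost,

$$\frac{f'(t_p)}{f(t_p)} = \frac{1}{T - t_p},$$

and the repaid condition is, for the purposes of the first player's
optimum, the unrepaid problem with horizon $2T$ (the bonus has the same
weight as own earnings and there is no conflict of interest over $t_s$).
Hence the repaid optimum is never earlier than the unrepaid one. Any
rational allocation has $t_p = T$ or $t_s = 0$; the overshoot case
($t_p = T$ with $t_s > 0$) can only occur for convex $f$, e.g.
$f(t) = t^2$.

### Numerical choices

* **Root form.** `solve_allocation()` finds the zero of
  $(T - t)\,f'(t) - f(t)$ rather than of $f'/f - 1/(T - t)$, avoiding a
  $0/0$ at curves with $f(0) = 0$.
* **Bracket and bisect.** The balance function is scanned on a 1,001-point
  grid; the last sign change is bracketed and bisected to
  $|\Delta t| \le 10^{-9} T$. Under log-concavity the marginal benefit is
  non-increasing and the marginal cost strictly increasing, so the sign
  changes at most once and bisection is safe. If the function is
  non-positive already at $t = 0$ (e.g. $f = e^{t/T}$), the optimum is 0.
* **Derivatives.** If `f_prime` is not supplied, central differences with
  step $10^{-6}(1 + |t|)$ are used.
* **Validation.** Curves are validated on a 1,001-point grid over
  $[0, 2T]$: non-negativity, strict increase, and second differences of
  $\log f$ below $10^{-8}$. Points with $f < 10^{-30}$ are exempted from
  the log-concavity and strict-increase checks so that curves with
  isolated zeros (such as $t^2$ at the origin) remain admissible.
  Violations are errors by default, downgradeable to warnings.
* **Independent oracle.** `grid_oracle()` maximizes the pay-off by brute
  enumeration (1-D for unrepaid; for repaid a coarse 2-D pass over
  $(t_p, t_s)$ followed by one refinement window at the requested step).
  The test suite demands solver-oracle agreement within $10^{-3} T$ on a
  battery of 22 linear, concave and convex-but-log-concave curves.

```{r analytic}
lc <- learning_curve(function(t) 1 + 2 * t, T = 1,
                     f_prime = function(t) rep(2, length(t)))
solve_allocation(lc, "unrepaid")
solve_allocation(lc, "repaid")
```

## The virtual-arrowhead simulation

The discrete task gives each agent $T = 50$ trials; the first trial is a
forced hunt, and each later trial is either **exploration** (modify the
arrowhead) or **exploitation** (hunt with it, observing a noisy score).
An arrowhead has three integer attributes (length, width, thickness) in
$[1, 100]$; the expected score is a unimodal quadratic,
$\mathrm{peak} - \sum_i w_i (x_i - o_i)^2$ floored at 0, and the displayed
score adds $\varepsilon \sim N(0, 5^2)$ noise, rounded and clamped to
$[0, 1000]$.

The agent is the classic WSLS learner: it remembers the last observed hunt
score and a direction sign per attribute; exploration moves one uniformly
chosen attribute $L = 5$ units in its memorized direction (clipped to
bounds); a hunt that scores *strictly* below the previous hunt reverses
the direction of the last-modified attribute (lose-shift), otherwise all
directions are kept (win-stay). Comparisons always use observed noisy
scores — agents never see the latent efficiency.

The searched strategy family alternates exploitation and exploration from
trial 1 to $2\tau$ and exploits thereafter ($0 \le 2\tau \le T-1$, so
$\tau \le 24$), mirroring the structure of the continuous optimum; the
unrestricted space of $2^{49}$ allocation sequences is not searched.
Writing $g(\tau)$ for the mean efficiency after $\tau$ explorations, the
expected totals are

$$W_{p,u}(\tau_p) = \sum_{\tau=0}^{\tau_p - 1} g(\tau) + (T - 2\tau_p)\,
g(\tau_p), \qquad
W_{p,r}(\tau_p) = \sum_{\tau=0}^{\tau_p - 1} g(\tau) + (2T - 2\tau_p)\,
g(\tau_p),$$

and `optimal_tau()` maximizes these over $\tau_p$, breaking ties toward
less exploration.

### Estimating g

`estimate_learning_curve()` runs the maximal alternating schedule
($\tau = 24$) for every agent and records the latent efficiency of the
design held immediately after each exploration; since any shorter schedule
coincides with the maximal one up to its switching point, one ensemble
pass yields all of $g(0), \dots, g(24)$. The default ensemble is 10,000
agents (a run takes well under a second); standard errors are returned per
$\tau$. One design convention worth noting: $g(\tau)$ is the efficiency
*after the $\tau$-th modification*, before the confirming hunt.

Randomness is split into per-agent L'Ecuyer-CMRG substreams
(`parallel::nextRNGStream`), so trajectories of the first $n$ agents are
invariant to the ensemble size, and a master seed fixes everything.

### The calibrated default landscape

The exact task coefficients behind the published optima are not public, so
the default landscape is **calibrated, not copied**:
`scripts/calibrate_landscape.R` scans symmetric offset/weight candidates
(common initial design, equal weights, peak 1000, noise SD 5) and the
shipped configuration — initial design $(30, 40, 35)$, optimum
$(85, 95, 90)$, weights $0.07$ — was selected because its 10,000-agent
learning curve places the optima at $\tau^* = 12$ (unrepaid/asocial) and
$\tau^* = 22$ (repaid), stably across master seeds. Intuition for the
shape: each attribute starts 55 units (11 exploration steps) from its
optimum, so the curve still rises, slowly, at $\tau \approx 22$ — enough
marginal gain to keep a repaid (horizon-$2T$) player exploring, but below
the steeper threshold that stops an unrepaid player after $\tau = 12$.
The configuration lives in `inst/extdata/default_landscape.yaml` and any
alternative can be supplied via `read_landscape_config()`.

```{r simulate}
g <- estimate_learning_curve(default_landscape(), n_agents = 2000, seed = 1)
optimal_tau(g, condition = "unrepaid")
optimal_tau(g, condition = "repaid")
```

(The 2,000-agent ensemble shown here keeps the vignette quick; the package
default, used by the tests and the acceptance script, is 10,000.)

### Conventions for edge cases

* Initial direction signs are independent uniform $\pm 1$ per attribute:
  the original rule is silent on initialization and this avoids biasing
  the search toward the optimum.
* The first hunt initializes the score memory and never flips a direction.
* Exact score ties are win-stay (the rule reverses only on *strictly less
  valuable* outcomes).
* A move clipped at an attribute bound still registers as the last
  modification; the flip, if any, comes from the subsequent losing hunt.
* If several hunts follow one exploration, a further losing hunt can flip
  the same attribute again — the simplest consistent reading.

## Transmission chains and the statistics pipeline

`run_chain()` hands the first generation's final design to the second
generation bit-exactly, with fresh agent memory. Trial logs — one CSV row
per participant-trial — are the single interchange format
(`write_trial_logs()` / `read_trial_logs()`), so synthetic and real logs
flow through identical analysis code: `exploration_counts()` extracts each
participant's $\tau$, `analyze_exploration()` runs the planned contrasts
(repaid vs asocial, unrepaid vs asocial) with Welch's unequal-variance
t-test at the Bonferroni-adjusted threshold $\alpha = 0.05/2 = 0.025$, and
Cohen's d uses the classical pooled SD (the convention adopted here; the
source analyses do not state theirs). `payment()` converts a cumulative
score $W$ (calories) to yen: $2W/50$ rounded up to the nearest 10, plus
the 700-yen show-up fee.

### The synthetic-participant generator

Real logs from the behavioural experiment are not distributed, so
`synth_participants()` emulates them in two modes.

* **Parametric** (the default study conditions): each participant's
  $\tau$ is drawn from a per-condition Normal — asocial
  $N(20.10, 3.51^2)$, unrepaid $N(19.45, 6.42^2)$, repaid
  $N(24.60, 5.56^2)$, $n = 20$ per condition, matching the reported
  first-generation group statistics — rounded and clipped to the
  behaviourally admissible range $[0, T-1]$. A participant's trajectory is
  then simulated by the WSLS agent: alternating while $\tau \le 24$, and
  for larger $\tau$ alternating to trial 48 and converting trailing
  exploitation trials to exploration. The extended range is deliberate:
  observed repaid participants averaged $\tau = 24.6$, *above* the
  alternating-family cap of 24, and truncating at 24 would both distort
  the configured group means and flatten the very contrast the pipeline
  exists to detect. Over-exploring humans demonstrably left the
  alternating pattern; the tail-conversion schedule is a minimal model of
  that behaviour.
* **Agentic**: $\tau$ is fixed per condition at the rational optima
  (12/12/22) and all variation comes from the stochastic WSLS dynamics;
  useful for trajectory-level and efficiency studies, degenerate by
  construction for between-condition $\tau$ tests.

What the generator does *not* emulate: individual differences in learning
rule or step size, deviations from the (possibly tail-converted)
alternating pattern at arbitrary positions, curiosity-driven switching,
or any prosociality structure. A passing pipeline therefore shows that
the statistics recover effects of the configured size under idealized
WSLS behaviour — not that the behavioural claims replicate.

```{r stats}
logs <- synth_participants(default_synth_config(n = 20),
                           landscape = default_landscape(), seed = 42)
analyze_exploration(logs)
```

## Problem sizes and test design

The test battery sizes are the package's own choices for a fast, sharp
suite: 22 curves in the analytic battery; 10,000-agent ensembles (three
seeds) for the headline optima; 1,500-4,000-agent ensembles for ordering
and consistency properties; an exact 648-path enumeration oracle for the
WSLS process on a tiny zero-noise instance ($T = 10$); 100 seeded
replicates for the significance-pattern power check. Monte-Carlo
assertions use 3-3.5 standard-error tolerances; exact contracts
(transmission hand-off, schedule layout, payments, strategy counts) are
asserted exactly.

## Known limitations

* The analytic module requires log-concave increasing curves; multimodal
  or stochastic learning curves are out of scope.
* The simulation searches only the alternating strategy family, as the
  framework prescribes; richer block strategies could in principle do
  better.
* The default landscape is a calibrated stand-in reproducing the
  published optima, not the original coefficients.
* Group comparisons assume independent participants; chain-paired
  second-generation data would need dependence-aware models.
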