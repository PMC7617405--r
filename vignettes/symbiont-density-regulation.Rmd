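---
title: "Host-controlled regulation of symbiont density: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-controlled regulation of symbiont density: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbdens)
```

## The model

symbdens studies a mutually obligate association between an iteroparous
female host and a compartmentalized, vertically transmitted endosymbiont.
The host's state is two-dimensional: energy reserves $E$ and within-host
symbiont density $W$, both bounded (default $[0, 20]$).  Time is discrete;
each step corresponds to one meal and runs through six events in order:

1. **Metabolic expenditure.** $E' = E - (\mu E + \omega)$: expenditure rises
   linearly with reserves ($\mu$, default 0.2) above a fixed floor
   ($\omega$, default 2 energy units per step).
2. **Reproduction.** On schedule steps (every `repro_interval` = 4 steps
   from `repro_first` = 8), and only if $E' \ge E_{crit}$ and
   $W \ge W_{crit}$ (both default 6), the host invests a fixed proportion of
   reserves, $E_{rep} = \lambda E'$ ($\lambda = 0.3$), and transmits a fixed
   proportion of its symbionts, $W_{rep} = \gamma W$ ($\gamma = 0.2$), to
   its offspring.
3. **Feeding.** The host gains $N = 8$ energy units; feeding is
   deterministic.
4. **Decision.** The host allocates $u \in [0, N]$ of the meal to the
   symbiont population.
5. **Symbiont update.** $W'' = W' + (u - \alpha W')\beta$ while $W' > 0$;
   an extinct population ($W' = 0$) cannot recover.  $\alpha = 0.5$ is the
   energetic maintenance cost per unit density, $\beta = 0.5$ the density
   gained per unit of net energy.
6. **Storage.** Unallocated energy is stored: $E''' = E'' + N - u$.

Survival from one step to the next is a product of saturating functions of
the end-of-step state,
$S = (1 - e^{-0.3 E'''})(1 - e^{-0.3 W''})$, so both starvation and symbiont
loss are lethal (the symbiont is obligate).  The immediate contribution to
host fitness is $B = E_{rep} W_{rep}$, accrued at the end of the step.

The host's optimal allocation policy maximizes expected lifetime fitness
via the dynamic-programming equation
$$H(E, W; u) = B(E, W; u) + S(E, W; u)\,V(E(t+1), W(t+1)),$$
iterated backwards from the horizon $T = 50$, where the terminal value is
the immediate fitness available at $T$.  `solve_policy()` returns the value
table $V(E, W, t)$ and policy table $u^*(E, W, t)$.

## Numerical choices

**Grids.**  The solver discretizes the state space at integer steps over
$[0,20]^2$ (configurable via `state_grid()`); the continuous action set is
approximated by a grid of step 0.1.  Successor states fall between nodes,
so $V$ is read by bilinear interpolation, clamped into the state bounds;
nearest-node snapping was rejected because the forward dynamics are
genuinely continuous-valued.  During simulation the policy itself is also
read by bilinear interpolation.

**Clamping.**  Stored states are clamped into $[0, E_{max}] \times
[0, W_{max}]$.  Intermediate quantities within a step ($E'$, $E''$, $E'''$,
$W'$, $W''$) are used unclamped — a starving host's negative $E'''$ must be
visible to the survival function, whose factors map negative arguments to
zero so that $S \in [0, 1]$ always holds.

**Tie-breaking.**  Where several allocations attain the same objective the
solver picks the largest.  This matters exactly where the objective is flat
— most prominently after a host's final reproductive opportunity, when no
future fitness can accrue and every action ties at $H = 0$.  An indifferent
host here passes surplus energy on to its symbiont, and this choice is what
produces the characteristic post-reproductive symbiont proliferation in the
extended-lifespan scenario; breaking ties toward the smallest allocation
would instead starve the symbiont to extinction the moment it stops paying.

**Decisions end at $T - 1$.**  The horizon step contributes only its
terminal reproduction; no allocation is made there.

## Scenarios

`scenario_config()` selects among five host-symbiont ecologies:

* **base** — the obligate mutualism above;
* **symbiont_optimal** — identical dynamics, but the solver maximizes
  symbiont fitness ($W_{rep}$ transferred) instead of host fitness;
* **non_essential** — no density threshold for reproduction
  ($W_{crit} = 0$), survival depends on an offset density
  ($W'' + 2$), and fitness is $0.5\,E_{rep} W_{rep} + 5$, the constant
  accruing at every time step.  We read the published fitness form
  literally; whether the constant should accrue only at reproduction is
  ambiguous, and neither reading changes the qualitative outcome (see
  "Known limitations");
* **temporary_benefit** — from host maturation ($t \ge 8$) survival
  depends on reserves alone; the symbiont retains value only through
  transmission to offspring;
* **post_reproductive** — the final reproductive event occurs at $t = 32$,
  well before the horizon.

## Forward simulation

`simulate_cohort()` starts ten hosts (configurable) from every initial
state on the integer grid $\{1..20\}^2$ — 4000 hosts — and iterates the
step dynamics under any of five allocation strategies: the optimal policy,
an imperfect implementation ($u \sim U(u^* - 1, u^* + 1)$, clamped),
a fixed allocation ($u = 3$), density-proportional allocation
($u = 0.3\,W$), and the symbiont-optimal policy.  Host fitness
$V_H = \sum_t B(t)$ and symbiont fitness $V_S = \sum_t W_{rep}(t)$ accrue
over the steps the host is alive.

Survival can be **stochastic** (a Bernoulli draw with probability $S$ at
the end of each step, after fitness accrues — the default for fitness
comparisons) or **deterministic** (no draws; every host reaches the
horizon), which gives reproducible trajectories for convergence and
perturbation analyses.  The simulator is vectorized across hosts with a
single seeded RNG stream and a fixed draw order (every host, dead or
alive, consumes its draw each step), so a cohort is bit-reproducible given
its seed and configuration.

Perturbation experiments (`simulate_perturbed_cohort()`) reset each
surviving host's state to its own $t = 1$ values at the start of the
chosen steps (default 7, 24, 39), before metabolic expenditure.  Measured
at the cohort mean, the gap to the unperturbed trajectory after a
full-range reset shrinks every reproductive cycle and is below 0.1 density
units from the fourth cycle on; individual hosts closer to the converged
band return faster.

## Plateau density

The level around which the symbiont density stabilizes is operationalized
by `plateau_density()` as the mean of $W$ over all time steps of the
reproductive phase (from the first reproductive event to the end of the
schedule), across surviving hosts.  We deliberately average over the whole
phase rather than over the reproduction instants alone: density peaks just
before each reproductive event, so the instant-only average sits at the
cycle peak (about 6.6 in the base case) rather than at the maintained
level (about 6.3) that the phase average recovers.

## Sensitivity analysis

`run_sweep()` varies ten parameters jointly by Latin-hypercube sampling
(`lhs_sample()`, exactly one draw per equal-width stratum per parameter)
over the ranges in `sweep_ranges()`, re-solves the policy and re-simulates
a cohort per sample, and correlates each parameter with the plateau density
(Pearson, two-sided $t$-test on $n - 2$ df).  Defaults: $n = 400$ samples,
the unique sample count consistent with jointly observed correlation/
p-value pairs for this analysis; 2 replicates per initial state (sweep
speed; the full 10 are available by argument).

Sweep cohorts use **stochastic** survival.  This matters: over wide
parameter ranges some samples make the symbiont uncontrollable
(e.g. $\alpha\beta > 1$ lets the density overshoot to extinction, which can
even be the host's optimal course — one large terminal reproduction), and
such hosts must die and leave the surviving-host average, as they do in the
full simulations.  Keeping them alive at $W = 0$ (deterministic mode)
reverses the apparent effect of the growth-efficiency parameter.  Samples
in which no host survives into the reproductive phase have an undefined
plateau and are excluded listwise from the correlations; with the default
ranges this removes the majority of samples (the ranges deliberately probe
beyond the viable region), so the effective correlation sample is smaller
than $n$.

## Strategy comparison

`compare_strategies()` takes one cohort per strategy, tests overall
differences in $V_H$ and $V_S$ with Kruskal-Wallis, all pairs with
two-sided Wilcoxon rank-sum tests, and summarizes strategies by mean, SD,
and compact letter display (letters are maximal cliques of the
not-significantly-different graph).  Because published pairwise tables of
this kind often show repeated p-values suggestive of a multiplicity
adjustment, both raw and Holm-adjusted matrices are returned; the letter
grouping uses the Holm matrix by default at the 5% criterion.

## What the simulations do and do not show

The cohort design (every integer initial state, ten replicates) emulates a
maximally diverse host population, so convergence of density across hosts
is a property of the policy, not of a narrow starting distribution.  The
generator does not emulate stochastic feeding, between-host interaction,
symbiont self-replication dynamics, immune-mediated symbiont removal, or
multiple symbiont populations; conclusions about real host-symbiont
systems (tsetse, aphids, weevils, corals) carry only insofar as energy
allocation is the dominant regulatory channel.

## Problem sizes

The packaged analyses use the 21 x 21 state grid with an action step of
0.1 (solve time well under a minute), 4000-host cohorts, and $n = 400$
sensitivity samples at 2 replicates per state.  These sizes reproduce the
model's headline quantities stably; all are arguments, not constants.

## Known limitations

* The base-case optimum holds the density plateau at about 6.3-6.4 with a
  converged oscillation of roughly 5.8-6.6 and an allocation cycle of
  roughly 2.3-4.4; the cycle's allocation peak is somewhat sensitive to
  the unstated grid and action resolution of the original analysis.
* Under the literal non-essential fitness form the solver maintains a
  higher density plateau (about 7.6) than the published account of that
  ecology (about 3.8).  The per-step fitness constant makes the objective
  proportional to expected lifespan, and marginal-survival analysis shows
  the lifespan-maximizing density is then 8-12 regardless of how the
  constant and scale are read; we document rather than force this
  disagreement.
* Our symbiont-optimal policy yields modestly higher symbiont fitness and
  lower host fitness than the host-optimal policy (about 15% each way),
  a statistically detectable gap at cohort size 4000; both strategies
  nonetheless vastly outperform fixed and proportional allocation for both
  parties.
* Compact letter displays are computed by exhaustive clique enumeration
  and are only intended for the small strategy sets used here.
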