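---
title: "Reputation and payoff inequality in dynamic network games: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reputation and payoff inequality in dynamic network games: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repnet)
```

## The model

`repnet` simulates a population of $N$ agents repeatedly playing an
$N$-person Prisoner's Dilemma on an interaction network. Each period every
agent chooses one action, cooperate (C) or defect (D), played against all
of its current neighbours; its payoff for the period is the *mean* of the
dyadic payoffs over those interactions (so payoffs do not scale with the
number of partners). The dyadic payoff matrix defaults to
$CC = 5$, $CD = 0$, $DC = 8$, $DD = 2$.

Agents carry one of three fixed behavioural types: a fraction $p_A$ are
persistent altruists (always cooperate), $p_D$ are persistent defectors
(never cooperate), and the remainder $p_R = 1 - p_A - p_D$ are conditional
cooperators. Conditional cooperators cooperate in the first period with
probability $\theta_0 + a_0 r$ and afterwards reciprocate: they cooperate
when the cooperation score of their observed partners is at least
$\theta_C - a_C r$, where $r$ is the length (in periods) of the visible
reputation window. Both reputation-adjusted quantities are clamped to
$[0, 1]$; at the default values the clamping is inert. With probability
$\varepsilon$ an agent executes the opposite of its intended action, and the
*executed* action is what enters payoffs, histories and reputations —
observers can only see what was done.

Two network regimes are supported:

* **Random rewiring** — the whole network is redrawn every period as an
  Erdős–Rényi graph with edge probability $m/(N-1)$ (expected mean degree
  $m$); partners are strangers each period.
* **Strategic updating** — after each period every agent may drop one
  neighbour whose last executed action was D; a dropped link dies
  unilaterally. New links require mutual consent: each agent nominates up
  to $2m - \mathrm{deg}$ candidates from its eligible pool, and a link
  forms only for mutual nominations, processed in random order and
  refused whenever it would push either endpoint above the hard cap of
  $2m$ partners. With probability $\gamma$ an agent skips its entire
  update for the period.

### Information structure

What a conditional cooperator can condition on depends on the reputation
window:

* With reputational information ($r \ge 1$), the records of the agent's
  *current* neighbours are public: the score is the mean, over current
  neighbours, of each neighbour's fraction of executed C actions over the
  last $\min(r, \text{completed periods})$ periods. Reputation also gates
  partner choice: nomination pools are filtered to agents whose
  reputation is at least $\theta_C$ (the unadjusted threshold).
* Without it ($r = 0$), an agent knows only its own experience: the
  last-period executed actions of its *previous-period* partners. In a
  persistent (strategically updated) network the two readings nearly
  coincide, but under random rewiring they are fundamentally different —
  new random partners are strangers, so defection against last period's
  partners cannot be punished by this period's. This asymmetry is what
  creates the "payback" channel that reputation opens in randomly rewired
  networks, and it is the package's deliberate reading of the
  no-information regime.

Dropping a defecting neighbour needs no reputation: one always observes
one's own partners' executed actions, so the drop rule operates at
$r = 0$ too, keyed to the neighbour's last-period executed action.

### Parameters and defaults

| symbol | meaning | default |
|---|---|---|
| $N$ | population size | 100 |
| $m$ | target average degree; cap $2m$ under strategic updating | 2 |
| $T$ | number of periods | 100 |
| $p_A, p_D$ | fractions of persistent altruists / defectors | — |
| $r$ | reputation window (periods); 0 = none | 0 |
| $\theta_0$ | initial cooperation propensity | $p_A$ |
| $\theta_C$ | reciprocation threshold | 0.5 |
| $a_0, a_C$ | reputation effects on propensity / threshold | 0.1, 0.05 |
| $CC, CD, DC, DD$ | dyadic payoffs (game units) | 5, 0, 8, 2 |
| $\varepsilon$ | execution-error probability | 0.005 |
| $\gamma$ | update-omission probability | 0.005 |

Setting $\theta_0 = p_A$ equates willingness to cooperate on a first
encounter with the probability of meeting an unconditional cooperator.
Validation accepts $\theta_0, \theta_C \in [0, 1]$ (closed): the reference
sweep protocol ties $\theta_0$ to each grid cell's $p_A$, which includes 0.

## Outcomes

Two group-level inequality outcomes summarise a run:

* **Dispersion** — the Gini coefficient of final accumulated payoffs,
  computed as the plain relative mean absolute difference
  $\sum_{ij} |x_i - x_j| / (2 n^2 \mu)$ with no small-sample correction.
  All-equal payoffs give 0; a single holder gives $(n-1)/n$, which is 1
  only in the large-$n$ limit. The index is scale invariant, which is what
  makes it comparable across experiments with different incentive scales.
* **Correspondence** — the Pearson correlation between each agent's
  cooperation rate (fraction of periods executing C) and its final payoff.
  When either vector is constant the correlation is undefined and recorded
  as `NA`; sweep-cell means *exclude* such runs (and report how many),
  rather than zero-imputing them, because constant-behaviour groups are a
  real phenomenon and imputation would bias the cell means.

## Numerical and procedural conventions

* **Tie-breaks.** Reciprocation uses $\ge$ ("at least"), so ties
  cooperate. Mutual-nomination processing order is randomised each period
  to avoid positional bias; consents beyond the degree cap are refused in
  that random order.
* **Isolates.** An agent with no partners earns 0 for the period (an
  empty average; exclusion is costly). An isolated conditional cooperator
  redraws its initial-cooperation probability each period rather than
  locking into an arbitrary absorbing action.
* **Strategy counts.** The composition is deterministic: largest-remainder
  apportionment of $(p_A, p_D, p_R) \cdot N$, ties broken in the fixed
  order altruist, defector, conditional. Grid cells with the same
  composition are therefore exactly comparable; only the assignment of
  types to agent indices is random.
* **Initial network.** Erdős–Rényi with edge probability $m/(N-1)$. Under
  strategic updating the degree cap is a structural constraint of the
  regime, so over-cap nodes in the initial draw (about 5% of nodes at
  $N = 100$, $m = 2$) have uniformly-chosen excess edges removed before
  play; afterwards no operation can breach the cap.
* **Drops before nominations.** Drops are computed simultaneously from the
  pre-update network; nominations are then computed from the post-drop
  network. An agent cannot renominate the partner it just dropped
  ("replace" means someone else) — for that period only.
* **No-history candidates.** With $r \ge 1$, agents with no recorded
  history are ineligible as partners: they cannot demonstrate the required
  cooperation record. (Within a run this never binds — everyone acts every
  period — but it fixes the API contract.)
* **Reproducibility.** One master seed determines everything. Replicate
  runs draw independent substream seeds up front, and sweeps consume them
  in a fixed iteration order, so a `run_sweep()` result is bit-identical
  for a fixed master seed. The compiled network kernels draw from R's own
  RNG stream, so `set.seed()` governs them too.
* **No update after the final period** — it could not affect any outcome.

## The meta-analysis layer

`compare_conditions()` mirrors the group-level re-analysis workflow: within
each experiment, every treatment condition is paired with the experiment's
control; the effect direction is the sign of the difference in *medians*
of the per-network outcome (medians by default, for coherence with the
rank-based test; means are an option), and each pair also gets a
Mann–Whitney U test of the per-network values. Across pairs, the exact
binomial sign test asks whether positive and negative directions are
equally likely; exact zero differences are dropped (standard sign-test
practice) and counted.

Conventions: the one-sided sign test is the upper tail $P(X \ge k)$; the
two-sided version doubles the smaller tail and caps at 1, which at a null
of $\tfrac12$ coincides with the minimum-likelihood rule. The Mann–Whitney
U counts pairs with $x_i > y_j$ plus half the ties; the p-value is exact by
complete enumeration of all $\binom{n+m}{n}$ group assignments when both
samples have at most 8 observations (a documented threshold chosen so the
enumeration stays under a few thousand splits), and otherwise uses the
normal approximation with tie correction and a 0.5 continuity correction.
The returned object reports which method was used.

## The synthetic experiment generator

Real group-level experiment datasets of this kind (networks nested in
conditions nested in experiments) are not distributable with the package,
so `generate_outcomes()` draws per-network $(G, \rho)$ pairs from
truncated-normal location-shift distributions: control networks centred at
$(g_0, \rho_0)$, treatments shifted by $(\Delta_g, \Delta_\rho)$, truncated
to $[0, 1)$ and $[-1, 1]$. The defaults (8 networks per condition, network
sizes in the tens, centres $g_0 = 0.3$, $\rho_0 = 0.25$, between-network
standard deviations 0.08 and 0.2, zero shifts) mirror the *orders of
magnitude* of published network cooperation experiments without claiming
to reproduce any study; the neutral zero-shift default makes the generator
a null model unless an effect is specified. The truncated-normal form is
the minimal distributional choice — nothing in the re-analysis methodology
depends on it — and every parameter is exposed.

What passing tests on generated tables do show: that the pairing,
direction, Mann–Whitney and sign-test machinery recovers designed effects
and stays calibrated under the null. What they cannot show: anything about
game-specific payoff scales, participant behaviour, or within-network
dependence structure in real experiments — the generator draws group-level
summaries directly, not individual play. `generate_from_simulator()`
closes part of that gap by using the agent-based model itself as the data
source, one simulated group per network row.

## Problem sizes used by the test suite

The suite favours a few deep, replicated checks over many shallow ones.
The composition-sweep check runs the full reference protocol
($N = 100$, $T = 100$) on the 6×6 grid with 100 replicate runs per cell
and condition — enough for cell means to be stable at the grid's effect
sizes. Directional engine properties use 200 replicate runs per arm;
null-calibration of the meta pipeline uses 1000 seeds; Gini is checked
against a brute-force pairwise oracle on 1000 random vectors (lengths up
to 200) and the exact Mann–Whitney path against full enumeration for all
sample sizes up to 7, with and without ties. `scripts/acceptance.R`
re-runs the sweep at 40 replicates per cell, which preserves every
directional contrast while keeping a single-CPU run short.

## Known limitations

* The model is a heuristic, fixed-strategy one: no learning, no evolving
  strategies, no memory of partner identity beyond the reputation window.
* Payoffs are per-interaction averages; settings where payoff scales with
  the number of partners (buyer–seller markets, preferential attachment)
  behave differently and are out of scope.
* Ties are unweighted and undirected; link costs are absent.
* The exact Mann–Whitney path is limited to small groups (both $n, m \le
  8$); larger groups use the corrected normal approximation, as is
  standard.
* With $p_A = 0$ and $\theta_0 = p_A$, cooperation collapses towards the
  error floor and both outcomes are dominated by noise; conclusions about
  that corner of the composition grid are correspondingly weak.
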