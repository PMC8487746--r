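# repnet

Agent-based simulation of how **reputation** shapes **payoff inequality**
in repeated network cooperation games, plus the group-level statistics to
analyse such experiments.

## The problem

Reputation is known to promote cooperation, and higher cooperation raises
average payoffs — but how are those payoffs *distributed*? `repnet` is for
researchers in evolutionary game theory, behavioural economics and
computational social science who want to study two distinct faces of
inequality in repeated social dilemmas:

* **dispersion** — how spread out final payoffs are, measured by the Gini
  coefficient `G = Σᵢⱼ |xᵢ − xⱼ| / (2 n² μ)` of payoffs accumulated over
  the game;
* **correspondence** — whether payoffs track behaviour, measured by the
  Pearson correlation between an agent's cooperation rate and its final
  payoff.

## The model

`N` agents play a repeated N-person Prisoner's Dilemma (default payoffs
CC = 5, CD = 0, DC = 8, DD = 2; per-period payoff is the *mean* over a
player's interactions). A fraction `p_A` are persistent altruists, `p_D`
persistent defectors, and the rest conditional cooperators who first
cooperate with probability `θ₀ + a₀·r` and then reciprocate when at least
`θ_C − a_C·r` of their observed partners cooperated, where `r` is the
reputation window (r = 0: no reputational information; agents know only
what their own previous partners did). Actions are executed with a small
error `ε`. The interaction network either gets **randomly redrawn** every
period (Erdős–Rényi, mean degree `m`) or is **strategically updated**:
agents drop a defecting neighbour, nominate replacements (filtered by
reputation when `r ≥ 1`), and new links form by mutual consent under a
hard degree cap of `2m`. See the vignette
(`vignettes/reputation-inequality-model.Rmd`) for the full specification.

A meta-analysis layer compares control (no reputation) against treatment
conditions across experiments: per-pair Mann–Whitney U tests (exact by
complete enumeration for small groups) and an exact binomial **sign test**
over the effect directions. A synthetic generator produces group-level
outcome tables with the nested structure of published experiments so the
pipeline is fully testable.

## A worked example

```r
library(repnet)

# mixed population, reputation window 1, strategically updated network
p <- sim_params(p_A = 0.1, p_D = 0.1, r = 1,
                mode = "strategic_updating", seed = 1)
summary(run_simulation(p))
#> Run summary (N = 100, T = 100, r = 1, strategic_updating)
#>   Gini of final payoffs      : 0.3667
#>   Pearson correspondence     : 0.9882
#>   mean cooperation level     : 0.6526
#>   mean final payoff          : 296.65

# same world without reputational information
p0 <- sim_params(p_A = 0.1, p_D = 0.1, r = 0,
                 mode = "strategic_updating", seed = 1)
summary(run_simulation(p0))
#> Run summary (N = 100, T = 100, r = 0, strategic_updating)
#>   Gini of final payoffs      : 0.5152
#>   Pearson correspondence     : 0.9835
#>   mean cooperation level     : 0.3526
#>   mean final payoff          : 166.95
```

In this run, reputational information nearly doubles the cooperation
level (0.65 vs 0.35) and mean payoffs, while the isolated defectors'
near-zero earnings keep correspondence almost perfect in both cases.
Single runs vary; replicated grids over population compositions come from
`run_sweep()`:

```r
sw <- run_sweep(grid = expand.grid(p_D = c(0.1, 0.3), p_A = 0.1),
                conditions = data.frame(r = c(0L, 1L),
                                        mode = "random_rewiring"),
                reps = 50, base = sim_params(0.1, 0.1), master_seed = 7)
sw$table[, c("p_D", "p_A", "r", "mean_gini", "mean_pearson")]
#>   p_D p_A r  mean_gini mean_pearson
#> 1 0.1 0.1 0 0.07635279   -0.9086713
#> 2 0.3 0.1 0 0.11120494   -0.9341036
#> 3 0.1 0.1 1 0.04399196   -0.5846417
#> 4 0.3 0.1 1 0.05370476   -0.5740111
```

Under random rewiring, reputation *lowers* dispersion (Gini drops in both
cells) and softens the negative correspondence: defection no longer goes
unpunished, because new partners can see last period's actions.

The meta-analysis layer works on any outcome table with columns
`experiment, condition, network, gini, pearson`:

```r
tab <- generate_outcomes(lapply(1:8, function(i)
  experiment_design(paste0("E", i), delta_g = -0.1, n_networks = 6)),
  seed = 42)
m <- compare_conditions(tab, outcome = "gini", alternative = "less")
m$n_negative; m$sign_test$p.value
#> [1] 8
#> [1] 0.00390625
```

A thin command-line front end (`inst/cli/repnet`) exposes `run`, `sweep`,
`meta` and `synth` subcommands over the same functions.

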