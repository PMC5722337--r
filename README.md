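# castesim

`castesim` is an agent-based simulator of the evolution of honest and
deceptive signaling in a socially stratified population, built for
researchers in behavioral ecology and evolutionary game theory who want
to study how *opportunistic punishment* — punishment that rewards the
punisher — interacts with social structure to maintain (or fail to
maintain) a reliable signaling system.

## The model

A society of N agents (default 3,000) is partitioned into three castes
that differ in true aggression level: caste 0 (low), 1 (medium), 2
(high). Each agent carries a fixed, possibly deceptive signal of its
aggression level — honest iff `signal == caste`. A caste `c` is
parameterised by four quantities:

| caste | endowment `E_c` | metabolic factor `m_c` | honest appropriation `h_c` | dishonest appropriation `d_c` |
|---|---|---|---|---|
| 0 | 50  | 0.050 | 0.25 | 0.50 |
| 1 | 75  | 0.075 | 0.50 | 0.75 |
| 2 | 100 | 0.100 | 0.75 | 1.00 |

Each tick is one asymmetric encounter. A focal agent *i* and an opponent
*j* are drawn uniformly at random; only the focal agent's resources
`R_i` ever change:

1. **Signaling** — the focal agent observes only the opponent's signal
   `s_j`.
2. **Fight or flight** — a *peaceable* signal (`s_j <` caste of *i*)
   always provokes a fight. Facing a strictly higher signal the focal
   agent flees; facing an equal signal it fights with probability
   `R_i / E_i` and flees otherwise. Fleeing costs `m_i * R_i`.
3. **Payoffs and punishment** — in a fight, the higher true caste wins;
   within a caste the richer agent wins (exact ties: fair coin). A
   winning focal agent gains `h_i * R_j` from an honest loser or
   `d_i * R_j` from a dishonest one — deception is punished, and the
   punisher profits. A defeated focal agent loses `h_i * R_i` (honest)
   or `d_i * R_i` (dishonest) of its own resources.
4. **Replication** — when `R_i` drops strictly below 10% of `E_i` the
   agent starves and is replaced by a same-caste newborn at full
   endowment whose signal is copied from the richer of two randomly
   drawn caste-mates (binary tournament).

Runs start with 85% of each caste signaling deceptively (the two wrong
signals equiprobable). Parameter sweeps multiply the columns of the
table above by a scale vector `[sE, sm, sh, sd]`; `[1,1,1,1]` is the
most severe punishment regime and `[0.1,0.1,0.1,0.1]` the mildest. The
fight-or-flight form, the flee-cost base and the defeat-loss attribution
are pluggable via `sim_config()`; the defaults above are the calibrated
forms (see the methods vignette in `vignettes/`).

## Worked example

```r
library(castesim)

cfg <- sim_config(ticks = 2e6, seed = 1)   # paper-scale default run
run <- run_sim(cfg)
glance(run)
#> # A tibble: 1 × 7
#>    seed   ticks n_deaths mean_age_at_death final_liars_0 final_liars_1 final_liars_2
#>   <int>   <dbl>    <int>             <dbl>         <int>         <int>         <int>
#> 1     1 2000000    30618           151244.             0             0             7
```

Under the most severe punishment regime, the 2,550 initial deceivers are
almost entirely purged by tick 2,000,000 (here 0/0/7 remain per caste),
at the cost of 30,618 starvation-replacement events whose mean age at
death was about 151,000 ticks. Replications and tidy summaries:

```r
runs <- run_replications(cfg, 5)
summarize_runs(runs)
#> <castesim_summary> 5 replicate(s), scale [1, 1, 1, 1], 2,000,000 ticks
#> # A tibble: 3 × 5
#>   caste caste_size mean_deaths mean_age_at_death mean_final_liars
#>   <int>      <int>       <dbl>             <dbl>            <dbl>
#> 1     0       1000      14499.           131507.              3.6
#> 2     1       1000       7224.           182527.              0.2
#> 3     2       1000       9308            153408.              6
autoplot(runs, what = "liars")   # grey replicates + black mean, per caste
```

Lower-level building blocks (`init_population()`, `step_sim()`,
`decide_engagement()`, `battle_outcome()`, `tournament_strategy()`, ...)
are exported and documented, and `run_sim(cfg, engine = "reference")`
runs a naive pure-R loop that reproduces the compiled engine
bit-for-bit. Egalitarian (single-caste) societies come from
`egalitarian_config()`, and `full_factorial_sweep()` crosses scale
levels over the four parameters (4 levels → 256 settings).

A thin command-line front end lives at `inst/cli/castesim.R`
(`run`, `sweep`, `egalitarian`, `summarize`, `plot` subcommands).

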