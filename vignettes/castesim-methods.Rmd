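---
title: "Honest signaling under opportunistic punishment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Honest signaling under opportunistic punishment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castesim)
```

## The scientific question

Reliable signaling is usually taken to be a precondition for a signaling
system to persist: if deception is common enough, receivers should
ignore the signal and senders should stop paying for it. One candidate
stabilising force is *strategic cost* — a deceptive signaler, once
caught, is punished. `castesim` implements a stylised dominance-contest
model, inspired by badge-of-status signaling in social insects, in which
punishment is *opportunistic*: the agent that defeats a liar extracts
extra resources from it, so punishing is profitable rather than
altruistic. The model asks whether such punishment alone can purge
deception, and how the answer depends on social stratification.

## Population and parameters

The population holds `N` agents (default 3,000) in three castes of fixed
size (default 1,000 each; a total not divisible by three assigns the
remainder to the lowest castes first, chosen for determinism). Caste is
an agent's true aggression level; its *signal* is the level it displays,
fixed for life. Four per-caste parameters govern the dynamics (defaults
in `default_caste_params()`):

* **endowment** (50/75/100 resource units): resources at birth; also the
  scale for the starvation threshold and the flight decision;
* **metabolic cost factor** (0.05/0.075/0.1, dimensionless): the cost of
  fleeing an encounter. It is not a model of metabolism; it exists so
  that perpetual flight is not viable;
* **honest appropriation** (0.25/0.50/0.75) and **dishonest
  appropriation** (0.50/0.75/1.00): the fraction of the relevant
  resource pool transferred when a fight is lost against, or won by, a
  given caste; the dishonest column always exceeds the honest one, which
  is the punishment premium.

A *scale vector* multiplies the four parameter columns across all castes
at once, which is how punishment severity is swept: `[1,1,1,1]` is the
severest regime, `[0.1,0.1,0.1,0.1]` the mildest. Initially 85% of each
caste signals deceptively, the two wrong signals equiprobable within
each caste; the 85% rate is applied per caste (not only population-wide)
because per-caste deception counts are the model's main observable and
should start at a known level in every caste.

## The encounter

One tick is one encounter. A focal agent and a counterparty are drawn
uniformly without replacement; **only the focal agent's resources
change**. Resource non-conservation is intentional: a winning focal
agent's gain is not deducted from the counterparty, which keeps the
update strictly asymmetric and makes an agent's fate depend only on what
happens when it is focal.

The focal agent fights whenever the opponent's signal is *peaceable* —
strictly below its own true caste. Equal signals are not peaceable:
flight remains possible between apparent equals when the focal agent is
poor. What happens against a non-peaceable signal is the model's main
free design choice, because the underlying behavioural description —
fight if your resources are high enough, flee more readily the poorer
you are, with a tendency to flee from displays of superior aggression —
does not pin down a functional form. The package therefore makes the
rule pluggable (`flee_prob_form`):

* `"signal_gated"` (default): flee deterministically from a strictly
  higher signal; against an equal signal fight with probability
  `resources / endowment`;
* `"linear"`: fight with probability `resources / endowment` against any
  non-peaceable signal.

Fleeing costs `met_cost_factor` times a base that is likewise pluggable
(`flee_cost_base`): the current resources (`"current"`, default,
a proportional decay), the endowment (`"endowment"`, a fixed per-caste
amount), or nothing at all — the factor taken as an absolute amount
(`"absolute"`). The `"absolute"` reading exists because the parameter is
stated in resource units in the original description of the model even
though its use is described as a portion of the endowment; both readings
are implemented.

Fights are decided by true aggression: the higher caste wins; within a
caste the richer agent wins; an exact resource tie is a fair coin. A
winning focal agent gains its own caste's appropriation fraction
(honest or dishonest column by the loser's honesty) of the
counterparty's holdings. For a *defeated* focal agent the governing row
is ambiguous in the verbal model ("resources are adjusted up or down
according to the appropriation tables"), so it is a third switch
(`defeat_loss_basis`): the winner's caste row (`"winner"`) or the focal
agent's own row (`"own"`, default). The honesty column is always the
loser's own.

### Why these defaults

The three switches were calibrated jointly against the original study's
published per-caste summary statistics (mean death counts and mean ages
at death under the severest and mildest regimes, and the wealth ratio of
surviving deceivers to honest signalers under intermediate punishment),
which `scripts/acceptance.R` recomputes. Two observations drove the
choice:

* Under the severest punishment the low caste must be the *longest*
  lived of the three despite losing every cross-caste fight. That is
  incompatible with charging a defeated agent the winner's appropriation
  row (a low-caste agent would forfeit 75–100% of its holdings to a
  high-caste winner and die within a handful of encounters) and points
  to the `"own"` attribution, under which low-caste defeats cost only
  25–50%.
* Under the mildest punishment the low caste must be nearly immortal
  (mean age at death close to the full run length). This requires both
  that low-caste agents not be dragged into unwinnable fights at full
  endowment (the `"signal_gated"` form) and that the flight cost decay
  proportionally with current holdings (`"current"`), which stretches
  the flee-only survival horizon to hundreds of encounters.

With these defaults the simulator reproduces the qualitative structure
of the published results — purge order (middle caste first), persistence
of high-caste deception, frozen high-caste deception under minimal
punishment, and the survivorship-driven wealth advantage of high-caste
deceivers — and most of the quantitative summaries to within tens of
percent; the test suite (`tests/testthat/test-acceptance.R`) asserts the
quantitative ones at a 10% tolerance and documents which remain outside
it. The alternatives stay available as configuration switches so the
sensitivity of any conclusion to these choices can be checked directly.

## Starvation and replacement

After the focal agent's resources are adjusted, it dies iff they fall
*strictly* below `death_threshold_fraction` (default 0.10) of its
endowment. The boundary is exact: an agent at precisely the threshold
survives. Only the focal agent's resources ever change, so the check
runs once per tick, for the focal agent. The replacement is immediate
and in place: a newborn of the same caste at full (scaled) endowment,
`birth_tick` set to the current tick, and a signal copied from the
richer of two candidates drawn uniformly *without replacement* from the
same caste, excluding the dying agent (resource ties broken by a fair
coin). Sampling without replacement and excluding the deceased are
choices the verbal model leaves open; both are the symmetric minimal
options. Two consequences follow and are asserted as invariants: caste
sizes never change, and a signal value absent from a caste can never
reappear in it (an all-honest caste is absorbing — and so is an
all-deceptive one, which matters at small population sizes; see below).

## Randomness and reproducibility

A run is a pure function of its configuration, including the seed. All
randomness flows through R's global RNG in a fixed documented order per
tick: pair draw (two uniforms), engagement (one uniform when the
resource-ratio rule is invoked), battle tie-break (one uniform on exact
ties), tournament (two uniforms plus one on ties). Index draws use
`floor(u * n)` so the compiled engine (Rcpp, `run_core`) and the naive
pure-R reference engine (`run_reference()`, a plain loop over the
exported primitives) consume identical streams and produce bit-identical
snapshot tables, death logs and final populations — asserted in the test
suite on a 30-agent, 10,000-tick instance and for the non-default rule
forms. Replicate seeds come from `spawn_seeds()`: a draw without
replacement from the 31-bit integers under the base seed, so replicate
`i` is reproducible in isolation.

Snapshots record, at tick 0, every `snapshot_interval` ticks (default
1,000) and the final tick, the count and mean resources of every
(caste, signal) cell; empty cells get a missing mean rather than zero.
Per-caste liar counts are derived sums (`liar_counts()`), change only at
replacement events, and are piecewise constant in between.

## What the simulator does and does not emulate

All data are synthetic by construction: the model is the object of
study, not a fit to field data. The defaults are the original study's
conditions (3,000 agents, 85% initial deception, 10% starvation
threshold, 2,000,000 ticks, 30 replications). Passing tests therefore
show that this implementation reproduces the model's internal dynamics,
not that real signaling systems behave this way: agents have no memory,
no reputation, no kin structure, no signal plasticity within a lifetime,
and encounters have no spatial or network structure.

## Numerical and scale choices

* The engagement probability clamps `resources / endowment` to [0, 1];
  resources are floored at zero after a flight cost.
* Exact resource ties (battle and tournament) are broken by fair coins;
  with continuous resource dynamics they essentially only arise between
  newborn agents at full endowment.
* Test-suite problem sizes: full-scale checks use 3,000 agents and
  2,000,000 ticks (single runs or 5–30 replications); stochastic
  trajectory properties use a reduced desk scale of 300 agents
  (100/caste), 200,000 ticks and 10 replications, which preserves the
  per-slot encounter intensity (about 667 focal picks per agent slot).
  At 100 agents per caste the all-deceptive absorbing state is reachable
  (the 15 initial honest signalers of a caste can drift to extinction,
  observed in roughly 3% of severe-punishment replicates), so
  monotonicity of deception in punishment severity is tested with
  rank-based significance tests rather than raw means, and the
  egalitarian caste-equivalence check compares replicate *bands* rather
  than mean curves.

## Known limitations

* The printed summary statistics of the original study are reproduced
  to within roughly 10–30% but not uniformly to 10%; the residual gap
  presumably reflects behavioural details of the original implementation
  (exact flight rule, cost base, rounding) that its verbal description
  does not determine. The pluggable switches bound this uncertainty.
* Rare-event counts (a caste with ~1 death per 2,000,000 ticks) are
  intrinsically unstable across implementations: tiny differences in the
  flight rule move them by an order of magnitude.
* The egalitarian societies of different castes are similar but not
  identical here: the caste-2-only society purges deception about twice
  as fast as the caste-1-only society in the transient, a visible
  consequence of its harsher appropriation parameters.
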