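---
title: "Multilevel selection dynamics in multitype group-structured populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel selection dynamics in multitype group-structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mlsim` simulates a population of `d` microbial types structured into `m`
groups, each with a carrying capacity of `n` individuals. Groups can be read
as hosts and individuals as members of their microbial communities:
selection acts on individuals through within-group competition, and on
groups through differential splitting, which is what makes the process a
multilevel-selection model rather than a well-mixed one.

Individuals interact only within their group, through an evolutionary game
encoded by a `d × d` payoff matrix `A = (a_ij)`: `a_ij` is the payoff a
type-`i` individual receives from one interaction with a type-`j`
individual. A focal type-`j` individual in group `g` plays against each of
the other `N_g − 1` group members (never against itself), so its payoff is
the average

    pi_j = (n_jg − 1)/(N_g − 1) · a_jj + sum_{k != j} n_kg/(N_g − 1) · a_jk,

where `n_jg` is the count of type `j` in group `g` and `N_g` the group
size. Payoff maps to fitness exponentially, `f_j = exp(beta · pi_j)`, which
keeps fitness positive for arbitrarily negative payoffs and lets the single
intensity parameter `beta` interpolate from neutral drift (`beta = 0`)
through weak to strong selection.

Each update event is one of two things:

* **Immigration** (probability `lam`): a type drawn uniformly from the
  `d`-type environmental pool is added to a uniformly drawn group.
  Immigration allows extinct types to reappear, so the long-run state is a
  balance of selection and recolonization rather than a fixation endpoint.
* **Replication** (probability `1 − lam`): a parent is drawn
  fitness-proportionally and a copy of it is added to its group. Within a
  group the replication probability of type `j` is
  `b_j = n_j f_j / sum_k n_k f_k`.

If the affected group now exceeds `n`, the overflow is resolved
immediately: with probability `q` the group **splits**, its members
assigned to two offspring groups by independent fair coin flips (redrawn
until both offspring have at least two members), and one other group is
removed to keep `m` constant; with probability `1 − q` a uniformly chosen
individual is **culled** from the group. Group-level selection is
emergent: groups whose members earn higher payoffs reach capacity sooner,
split more often, and displace other groups. The total population size
consequently fluctuates between `2m` and `mn`.

## Classifying pairwise interactions

Rather than labelling interactions ecologically (mutualism, parasitism,
...), each unordered pair of types is classified by the dynamical outcome
of its `2 × 2` subgame `(a_ii, a_ij; a_ji, a_jj)` under two-type replicator
dynamics, which is fully determined by two invasion conditions — rare `i`
invades resident `j` iff `a_ij > a_jj`, and vice versa:

* **dominance** — exactly one type invades: it excludes the other from any
  interior starting frequency;
* **bistability** — neither invades: each type is stable when common, and
  the winner depends on the initial frequencies (the unstable interior
  point sits at `x* = (a_ij − a_jj) / (a_ij − a_jj + a_ji − a_ii)`);
* **coexistence** — both invade: the same `x*` expression is a stable
  interior equilibrium.

With i.i.d. continuous entries the two conditions are independent fair
coins, so a random matrix has on average 50% dominance, 25% bistability and
25% coexistence pairs — the baseline against which realized interaction
frequencies in simulations are compared. Exact ties among the compared
entries are classified *degenerate* and excluded from frequency
denominators: they have probability zero under the Gaussian generator, but
silently assigning them a class would corrupt baselines computed on
hand-crafted integer matrices. The classifier is validated in the test
suite against numerically integrated replicator dynamics; for bistable
pairs the integration endpoint depends on which side of `x*` the start
lies, which the validation accounts for.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `d` | types in the pool | — | study-specific; large `d` samples all interaction classes |
| `m`, `n` | groups, carrying capacity | — | the structure under study; `n >= 4` keeps every overflow splittable |
| `beta` | selection intensity | 1.0 | intermediate selection: payoff differences matter without being quasi-deterministic |
| `lam` | immigration probability | 0.1 | large enough to maintain diversity, small enough that selection (not immigration) drives dynamics |
| `q` | splitting probability | 0.001 | "rare splitting": group events much slower than individual events; `q = 1` is the frequent-splitting regime |
| `sigma2`, `mu` | payoff entry distribution | 1, 0 | standard-normal entries give a wide, unbiased range of interactions |
| `last_k_snapshots` | abundance-averaging window | 15 | long-run time-averaging convention used throughout |

Time is measured in update events, and snapshots are indexed by the event
clock: events are the only well-defined clock in the process, since
"generations" have no fixed meaning when group sizes fluctuate.

## Design choices that were genuinely open

* **Who replicates, globally?** The within-group replication probability
  `b_j` does not by itself determine how the group containing the parent is
  chosen. `mlsim` defaults to fitness-proportional selection over *all*
  individuals in *all* groups (`parent_selection = "global"`), whose
  restriction to one group is exactly `b_j`. The alternative — a uniform
  group, then `b_j` within it — would equalize growth rates across groups
  and erase the between-group component of selection (fitter groups could
  no longer reach capacity faster); it remains available as
  `parent_selection = "group-uniform"` for comparison.
* **Which group dies after a split?** "Another group is removed" is read as
  excluding both offspring (`removal_pool = "exclude-offspring"`), since
  removing an offspring would partly undo the split being described; the
  uniform-over-all-groups alternative is the `"all"` switch.
* **Single groups never split.** With `m = 1` there is no other group to
  remove, so overflow always culls, whatever `q` says.
* **Immigration into a full group** is permitted and can itself trigger the
  overflow rule, which is stated on group size, not on event kind.
* **Group similarity** is mean pairwise Jaccard on presence sets — a
  richness-flavoured measure; the abundance-weighted Bray–Curtis similarity
  is available as an option.
* **Realized interaction frequencies** weight a co-occurring pair `{i, j}`
  in a group by its number of interacting individual pairs,
  `n_ig · n_jg`; a presence-based (co-occurrence) estimator is available
  as an option.
* **Shannon index** uses the natural logarithm, the ecological convention.
* Ties for the most abundant type break toward the lowest type index,
  deterministically.

## Numerical and reproducibility choices

All randomness in a run derives from the single `seed` through R's global
RNG, consumed in a fixed documented order (event kind → actor → placement →
overflow resolution), so a `(config, matrix)` pair reproduces its
trajectory bit for bit. The compiled engine and the pure-R reference
engine consume the stream identically — cumulative weight sums and payoff
sums are accumulated in extended precision to match R's `sum()`/`cumsum()`
internals — and the test suite asserts that their trajectories are
`identical()`. Split allocation uses full rejection sampling (the whole
allocation is redrawn when an offspring would be smaller than 2), which is
the distribution stated by the model, not a repair heuristic. Degenerate
singleton groups, unreachable under the documented dynamics, are defined
to have payoff 0 (fitness 1) so defensive code paths cannot crash.
Downstream classification compares matrix entries directly rather than
simulated payoffs, so no floating-point tolerance enters the classifier.

## What the synthetic data does and does not emulate

The Gaussian payoff matrix is the model's own notion of a "random
community": unbiased, fully connected, with all interaction classes
present in known proportions. Real microbial interaction networks are
sparse, structured (e.g. cross-feeding chains), and context-dependent;
none of that is emulated, and conclusions from these simulations are about
the multilevel-selection mechanism, not about any particular community.
Likewise the environmental pool is uniform over all `d` types, so
immigration is a neutral force; a structured pool would couple the two.

The package's stochastic trend checks run scaled-down study conditions
chosen once: `d = 200` types, the `N = mn = 120` configurations
(`(m, n) = (6, 20)` group-structured vs `(1, 120)` single-group),
`beta = 1`, `lam = 0.1`, 150 000 events with a snapshot every 1 000, the
second half of each run as the long-run window, last-15-snapshot abundance
averaging, ten seed-paired replicates sharing one matrix realization.
Under these conditions the qualitative results — group structure raises
realized bistability and suppresses coexistence; rare splitting raises
richness and Shannon diversity while frequent splitting (`q = 1`) lowers
them; long-run abundance correlates positively with self-payoff — are
asserted as majority votes over the replicate pairs, which is the
appropriate strength of claim for stochastic orderings at this scale.

## Known limitations

* No migration between groups (horizontal transmission); the only flow of
  types is vertical (splits) and environmental (immigration).
* Selection acts at birth only; the culled individual is uniform, so there
  is no selection at death.
* One fragmentation mode: binary fair splitting at `n + 1`.
* Pairwise games only; higher-order interactions are not represented.
* The event-driven process has no absolute timescale, so quantities with
  units of time are only comparable between runs with matched event
  budgets.
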