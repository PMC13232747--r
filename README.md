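# mlsim

Stochastic simulation of **multilevel selection in multitype
group-structured populations**, modelled on host-associated microbial
communities: many microbial types, structured into groups (hosts), with
selection acting both within groups (payoff-driven replication) and
between groups (differential splitting).

The package is for theoretical ecologists and evolutionary modellers who
want to ask how group structure reshapes *which kinds of interaction*
(dominance, bistability, coexistence) are selected in a community, and
what that does to diversity.

## The model in brief

A population of `d` types lives in `m` groups of carrying capacity `n`.
Individuals interact within their group through an evolutionary game with
payoff matrix `A = (a_ij)`; the payoff of a type-`j` individual in group
`g` is its average payoff against the other `N_g − 1` members,

```
pi_j = (n_jg − 1)/(N_g − 1) · a_jj + Σ_{k≠j} n_kg/(N_g − 1) · a_jk ,
```

mapped to fitness as `f_j = exp(β · pi_j)`. At each event, with
probability `λ` an immigrant of a uniformly drawn type arrives from the
environmental pool; otherwise an individual replicates, drawn
fitness-proportionally (within a group this is `b_j = n_j f_j / Σ_k n_k
f_k`). A group that exceeds `n` either splits in two (probability `q`,
with another group removed to keep `m` constant) or loses one random
individual. Every unordered type pair is classified by the dynamical
outcome of its 2×2 subgame — dominance, bistability, or coexistence — and
simulation output is summarized by realized interaction frequencies among
co-occurring individuals, richness, Shannon diversity, group similarity,
homogeneous-group fraction, abundance rankings and leader turnover.

See the vignette (`vignettes/multilevel-selection.Rmd`) for the full
account of the model, the design choices and their rationale.

## Worked example

```r
library(mlsim)

A <- generate_matrix(d = 200, seed = 7)       # i.i.d. Normal(0, 1) payoffs
tab <- classify_all(A)
round(baseline_frequencies(tab), 4)
#>   dominance bistability coexistence
#>      0.4980      0.2556      0.2464
```

The matrix baseline is close to the exact 1/2, 1/4, 1/4 expectation for
i.i.d. continuous entries. Now simulate a group-structured population
(6 groups of up to 20, rare splitting) and summarize the long run:

```r
cfg <- sim_config(d = 200, m = 6, n = 20, beta = 1, lam = 0.1, q = 0.001,
                  seed = 1, n_events = 150000, sample_every = 1000,
                  burn_in = 75000)
traj <- run_simulation(cfg, A)
traj
#> Simulation trajectory: 151 snapshots over 150000 events (d = 200, m = 6, n = 20)
#>   events: 14785 immigration, 135215 replication, 149 split, 147058 cull

metrics_report(traj, A = A, table = tab)
#> Metrics report (long-run averages, event clock >= 75000 )
#>       total_richness  mean_group_richness        shannon_index
#>              24.5000               4.9627               1.6156
#>     group_similarity homogeneous_fraction
#>               0.1459               0.1404
#> Realized interaction frequencies:
#>   dominance bistability coexistence
#>      0.4691      0.4044      0.1265
#> ...
```

Among individuals that actually share a group, bistable interactions are
strongly enriched (0.40 vs the 0.26 matrix baseline) and coexistence
interactions depleted (0.13 vs 0.25): group structure selects pairs that
exclude each other locally, while different types colonize different
groups — which is also why total richness (≈ 24 types) stays well above
what a single group of the same total size maintains. Single runs are
noisy; the test suite asserts these orderings as majorities over ten
seed-paired replicates.

## Command-line interface

A thin Rscript front end covers the whole pipeline:

```sh
Rscript inst/cli/msim.R all --d 200 --m 6 --n 20 --beta 1.0 --lam 0.1 \
    --q 0.001 --events 150000 --seed 1 --out run1/
```

writes the payoff matrix, trajectory, interaction edge list, metric
tables, event log and a provenance manifest into `run1/`. Subcommands
`generate-matrix`, `simulate`, `classify` (with `--baseline` and
`--graphml`) and `analyze` run the stages separately. All artifacts are
plain tab-separated text with 0-based indices.

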