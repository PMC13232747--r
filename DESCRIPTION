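Package: mlsim
Title: Multilevel Selection Dynamics in Multitype Group-Structured
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of evolutionary dynamics in a
    population of many types structured into groups, as a model of
    host-associated microbial communities under multilevel selection.
    Individuals interact within their group through an evolutionary game
    given by a payoff matrix; replication is fitness-proportional with an
    exponential payoff-to-fitness mapping, immigrants arrive from an
    environmental pool containing all types, and groups exceeding their
    carrying capacity either lose a random individual or split in two
    (with another group removed to keep the group number constant).
    Includes a classifier of pairwise interactions by their dynamical
    outcome (dominance, bistability, coexistence), diversity and
    interaction-frequency metrics on simulated trajectories, delimited-
    text input/output for all artifacts, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
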