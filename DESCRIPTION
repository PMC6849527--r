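Package: dispnet
Title: From Frugivore Visitation Networks to Seed-Dispersal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for converting quantitative plant-frugivore visitation
    networks into seed-dispersal networks by labelling the functional outcome
    of every link (seed dispersal, pulp pecking or seed predation), pruning
    non-mutualistic links, and quantifying the structural consequences.
    Implements weighted network-level metrics (size, weighted connectance,
    weighted NODF nestedness, H2' specialization, Barber bipartite modularity
    with an LPAwb+ search), species-level metrics (degree, interaction
    frequency, d', species strength), Patefield and fill-conserving quasiswap
    quantitative null models with delta-transformation, a topological
    coextinction model with robustness and per-plant resilience, one-tailed
    paired Wilcoxon and Spearman tests with a Bernoulli-process multiple-test
    probability, and a seeded generator of realistic labelled visitation
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
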