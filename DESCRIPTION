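Package: calfnet
Title: Proximity-Based Social Network Analysis for Group-Housed Dairy Calves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds weighted social proximity networks for group-housed dairy
    calves from high-frequency indoor-positioning data and carries the full
    analysis chain: cleaning and smoothing of 1 Hz pen coordinates, dyadic
    association indices robust to missing fixes (simple-ratio index over
    fixed 3-minute windows aggregated into 4-day periods), node-level
    sociality measures (strength, social time, eigenvector centrality,
    closeness, coefficient of variation in association), permutation
    inference for network stability (Mantel/QAP) and social differentiation
    (data-stream permutation of within-window proximity groups), dyadic
    assortment regression with multiple-membership node random effects
    fitted by an in-package Gibbs sampler, and node-level linear mixed
    models with Benjamini-Hochberg correction. A synthetic-data module
    simulates pen trajectories, step-down weaning schedules and respiratory
    health scores with planted social structure so the whole pipeline is
    testable without proprietary sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    lme4,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
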