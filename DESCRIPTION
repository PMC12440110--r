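Package: mesoinfluence
Title: Reinforcement-Learning Modeling and Dependency Network Analysis of
    VTA-Centered Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying mesocorticolimbic network influence and
    bi-valent reward learning. Simulates two-armed probabilistic bandit
    behavior (gain, loss and neutral trials under 80/20 contingencies) and
    multivariate region-of-interest time series with a configurable
    directed hub, fits hierarchical Bayesian Q-learning models (single or
    valence-specific learning rates, optionally with group-level
    hyperparameters per clinical group) by adaptive MCMC, compares models
    with WAIC, runs posterior predictive checks and parameter recovery,
    and implements Dependency Network Analysis (DEPNA): partial-correlation
    based correlation influence, node dependency matrices,
    influencing/influenced degrees, and covariate-adjusted directed
    influence graphs, together with the surrounding association layer
    (seed-to-ROI Fisher-z connectivity, adjusted group differences and
    partial correlations, Benjamini-Hochberg FDR, rank-sum tests, mixed
    effects learning curves, cross-state Spearman correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    igraph,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
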