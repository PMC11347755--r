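Package: steeprank
Title: Dominance Hierarchy Steepness and Rank-Related Fitness Benefits
Version: 0.1.0
Authors@R: person("steeprank", "maintainers", email = "steeprank@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying dominance hierarchy steepness from win-loss
    sociomatrices with four algorithms (Dij-based normalized David's scores,
    randomized Elo-rating repeatability, and Bayesian Elo-rating and David's
    score surrogates with credible intervals), Landau-type linearity testing,
    Fisher-Z effect-size construction for rank-benefit correlations, and
    phylogenetic multilevel meta-regression with known sampling variances,
    model-comparison likelihood-ratio tests, heterogeneity and phylogenetic
    signal statistics, and publication-bias regressions. Includes a synthetic
    data generator with known ground truth for end-to-end validation and a
    command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
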