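Package: crossbench
Title: Statistical Methods and Simulation Benchmarks for Small-Sample
    Cross-Over Trials with Repeated Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis methods and a simulation benchmark for two-treatment,
    two-period cross-over trials with four repeated measurements per period
    and very small sample sizes, as encountered in rare-disease research.
    Implements generalized pairwise comparisons (univariate, prioritized and
    non-prioritized scoring; matched and unmatched pairing) with the net
    treatment benefit and exact or Monte-Carlo permutation inference, the
    conditional sign test, rank-based relative effects with the ANOVA-type
    statistic for treatment-by-time interaction, a GEE-type marginal model
    with bias-corrected sandwich covariance and Wald tests, and AIC-weighted
    model averaging with a permutation test. A seeded generator of trial-like
    overdispersed, serially correlated count and ordinal outcomes, a
    block-permutation engine for type-I-error simulation, and effect
    injection for power scenarios drive a reproducible method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
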