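Package: micrometa
Title: Meta-Analysis of Microbial Community Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for joint analysis of microbial abundance profiles across
    sequencing batches and studies: covariate-adjusted, zero-inflated
    empirical-Bayes correction of batch effects on count profiles;
    per-study differential-abundance models pooled by fixed- and
    random-effects meta-analysis, with moderator (interaction) and ordinal
    severity contrasts; unsupervised discovery of discrete population
    structure via prediction strength and its cross-study generalization;
    unsupervised discovery of continuous population structure via networks
    of correlated principal-component loadings; a zero-inflated log-normal
    community simulator with moment-preserving metadata spike-ins; and a
    PERMANOVA-based evaluation harness with blocked permutations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    lme4,
    metafor,
    permute,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
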