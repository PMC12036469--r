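Package: somnotype
Title: Sleep Embedding Risk Stratification from Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for deriving risk groups from overnight
    polysomnography. Provides a synthetic cohort generator with planted group
    structure, zero-phase elliptic preprocessing of multichannel signals,
    a patch-tokenized multi-task transformer that embeds each 30-second epoch,
    distributional-distance (energy / earth mover's) consensus clustering of
    variable-length embedding matrices into ordinal risk groups, a spectral
    sleep-fragmentation statistic, gradient-boosted prediction of cluster
    membership from standard summary metrics, and propensity-weighted Cox and
    Kaplan-Meier outcome analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    nnet,
    rlang,
    signal,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    cluster,
    jsonlite,
    mclust,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
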