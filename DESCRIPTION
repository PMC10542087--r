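Package: dfcstates
Title: Dynamic Functional Connectivity States and Time-Varying Network
    Topology for Parcellated fMRI Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity (dFC) analysis
    for two-group cohorts of parcellated ROI time series: temporal
    preprocessing (volume discard, linear detrend, zero-phase band-pass),
    windowed Pearson/Fisher-Z connectivity, K-means connectivity states
    with dwell-time and fractional-occupancy statistics, covariate-adjusted
    edgewise group contrasts with network-based-statistic (NBS)
    family-wise correction, and across-window variance of graph-theoretic
    metrics over a sparsity ladder.  Includes a synthetic cohort generator
    with a hidden-Markov covariance-switching model so that every stage of
    the pipeline can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
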