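Package: commdyn
Title: Dynamics of Causal Inter-Areal Communication from Paired Silencing Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired two-area spiking recordings with
    transient optogenetic silencing of one area. Quantifies per-neuron
    silencing effects with bootstrap significance, go/no-go behavioral
    metrics (d-prime with shuffle chance levels, onset-corrected reaction
    times), encoding models linking silencing effects to cell properties,
    regularized linear-discriminant communication directions and activity
    directions with cross-validated cosine-similarity dynamics, a Poisson
    time-invariant null simulation, Bhattacharyya influence magnitudes,
    windowed principal-component geometry, and exponential decay and
    permutation statistics on similarity lag profiles. Includes a synthetic
    two-area spiking simulator with exported ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    Rcpp,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
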