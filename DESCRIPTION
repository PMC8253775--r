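Package: burstnet
Title: Bursting Synchrony and Effective Connectivity Analysis of Neuronal
    Calcium-Imaging Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous activity of cultured neuronal
    networks recorded by calcium fluorescence imaging. Normalizes fluorescence
    to DFF, infers spike onsets with a Schmitt trigger, quantifies collective
    dynamics through the global network activity (GNA), network-burst catalogs
    and the ratio of extreme bursting events against a control reference,
    infers directed effective connectivity with generalized transfer entropy,
    and characterizes functional organization through Louvain communities, the
    community statistic Q, and degree-distribution comparisons
    (Kullback-Leibler divergence, Kolmogorov-Smirnov test). Includes a
    synthetic-data generator for ground-truth rasters and calcium traces, and a
    spatially-embedded conductance-based network simulator with dopaminergic
    neurite pruning for in silico perturbation experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
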