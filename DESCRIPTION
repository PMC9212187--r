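Package: connselect
Title: Evolutionary Feature-Subset Selection for Functional-Connectivity
    Graph Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discriminating two subject groups
    from resting-state functional-connectivity graph measures. ROI time
    series are band-pass filtered, turned into Fisher z-transformed
    correlation matrices and thresholded binary brain graphs; seven
    node-level graph measures (degree, betweenness, path length,
    clustering, cost, local and global efficiency) are assembled into a
    per-subject feature vector. Fixed-cardinality feature subsets are then
    searched by five evolutionary algorithms (genetic algorithm, NSGA-II,
    ant colony optimization, simulated annealing, particle swarm
    optimization) and a Welch t-test baseline, using the cross-validated
    accuracy of a two-hidden-layer perceptron trained with
    Levenberg-Marquardt backpropagation as the wrapper fitness. Includes a
    synthetic-cohort generator with known ground truth, accuracy-versus-
    subset-size experiments, feature-presence profiling and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
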