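Package: docnet
Title: Graph Topology of Resting-State Brain Networks in Disorders of
    Consciousness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for resting-state functional-network analysis
    of disorders of consciousness. Builds density-thresholded weighted brain
    graphs from nodal BOLD time series (detrending, Chebyshev band-pass
    filtering, nuisance regression, Fisher-z correlation), computes nodal and
    network-level topological metrics normalized against degree-preserving
    random networks (connectivity strength, betweenness, degree,
    small-worldness), profiles connectivity strength by Euclidean inter-node
    distance, classifies conscious state (VS/UWS, MCS, control) with
    one-vs-rest linear support-vector machines under leave-one-out
    cross-validation and permutation testing, and reproduces the associated
    group statistics (two-way and one-way ANOVA with Tukey post-hoc tests,
    baseline-referenced correlations, permutation tests with FDR control).
    Includes a synthetic cohort generator that emulates the group-dependent,
    distance-dependent covariance structure the analysis assumes, so the full
    pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
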