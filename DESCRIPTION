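Package: netmapr
Title: Population-Level Functional Brain Network Mapping and Cross-Cohort
    Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping large-scale functional brain networks from
    resting-state functional connectivity and for benchmarking their
    reproducibility across independent cohorts. Implements framewise
    displacement based motion censoring with contiguity rules, a
    demean/detrend, spectral interpolation, nuisance regression and
    band-pass denoising chain, vertex- and parcel-level group-average
    correlation matrices, multi-density map-equation (Infomap-style)
    community detection with Jaccard template matching and
    sparsest-threshold consensus labelling, winner-take-all assignment of
    subcortical voxels to cortical networks, and a similarity suite
    (Pearson matrix correlation, normalized mutual information, Dice
    coefficient, spherical spin-permutation nulls, Mantel label-permutation
    tests, participation coefficient). A synthetic-cohort generator with
    planted networks, motion traces and demographics enables desk-scale,
    fully reproducible split-half and cross-group experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
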