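Package: connsig
Title: Resting-State Connectivity Signatures via Multiclass Pattern Analysis
Version: 0.1.0
Authors@R: person("connsig", "maintainers", email = "maintainers@connsig.dev",
    role = c("aut", "cre"))
Description: A tested pipeline for three-group (schizophrenia patient /
    healthy sibling / healthy control) resting-state functional-connectivity
    classification: temporal preprocessing of regional BOLD time series
    (initial-volume discard, Chebyshev Type I band-pass, nuisance
    regression), whole-brain Pearson connectivity features, PCA plus
    one-against-rest linear support vector machines with leave-one-out
    cross-validation and a label-permutation null, and reconstruction of
    discriminative connectivities into state, trait, and compensatory
    signature sets. Includes a synthetic three-group cohort generator with
    planted, recoverable edge effects standing in for undeposited fMRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
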