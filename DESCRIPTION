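Package: pharmaconn
Title: Pharmacological Resting-State Functional Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pharmacological resting-state fMRI cohorts at
    the grayordinate level: temporal filtering, nuisance regression with and
    without global signal regression (GSR), motion scrubbing, global brain
    connectivity (GBC) and seed-based functional connectivity maps, global
    signal beta topography, permutation-based group inference with
    threshold-free cluster enhancement (TFCE), rank-conjunction analyses,
    network summaries, behavioural correlations, and spatial matching of
    contrast maps against cortical gene-expression maps. Includes a synthetic
    multi-subject, multi-condition BOLD cohort generator with ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    RNifti,
    optparse
Config/testthat/edition: 3
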