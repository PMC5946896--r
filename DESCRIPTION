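Package: semdecode
Title: Cross-Language and Cross-Modality Semantic Decoding of fMRI Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-voxel pattern analysis (MVPA) pipeline for testing whether
    concept-evoked brain activation patterns generalise across languages and
    stimulus modalities in bilinguals. Provides a synthetic multi-subject
    BOLD/beta-pattern simulator with controllable shared-semantic,
    language-specific and modality-specific signal regions; a first-level
    general linear model with canonical double-gamma HRF, temporal
    derivatives and discrete-cosine high-pass set; spherical-searchlight and
    region-of-interest k-nearest-neighbour cross-classification with
    leave-one-run-out folds averaged over both train/test directions;
    mask-aware Gaussian smoothing of accuracy maps; group-level one-sample
    t-maps against chance with sign-flip max-cluster-extent permutation
    correction; and ROI inference via within-run label permutation plus
    bootstrap group nulls with Benjamini-Hochberg FDR control. Includes
    stimulus-set validation utilities enforcing zero lexical overlap between
    translation equivalents (normalised Levenshtein distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    RNifti,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
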