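Package: refsca
Title: Reference-Based Sparse Component Analysis for Omics Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes mass-spectrometry and gene-expression samples with a
    reference-based additive linear mixture model. Each test sample is paired
    with a class-reference profile (the average of the control or disease
    group) to form a two-row mixture, which is factorized by two-stage sparse
    component analysis: single-component points are detected with an
    analytic-signal directionality criterion, the non-negative 2xM mixing
    matrix is estimated by complete-linkage hierarchical clustering under
    cosine distance, and the MxK source matrix is recovered by accelerated
    iterative shrinkage-thresholding with the penalty specified relative to
    its maximal useful value. Disease- and control-specific components are
    selected automatically from the mixing angles, without using labels, and
    evaluated by repeated stratified two-fold cross-validation with support
    vector machines. Includes a simulator of orthogonal-component mixtures
    with sector-confined mixing angles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
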