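Package: braindecomp
Title: Feature Decomposition and Kernel Discriminant Analysis for MR Brain
    Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage classifier for voxel-wise gray-matter density features
    from structural MR brain images. Training features are decomposed into a
    class-specific dictionary, a non-class-specific (confound) low-rank term
    and a sparse error by an augmented-Lagrange-multiplier solver for a
    nuclear-norm plus L1 regularized program; the class-specific components
    are then mapped to a linearly separable space by Gaussian-kernel
    discriminant analysis in spectral-regression form (with an optional
    cardinality-constrained sparse variant) and classified by nearest
    neighbor. Includes volume preparation (Gaussian smoothing, block-mean
    downsampling, vectorization), training-only t-test feature screening and
    biomarker mapping, a synthetic cohort/volume generator emulating the
    model's generative assumptions, and a stratified k-fold cross-validation
    harness reporting accuracy, sensitivity, specificity and AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
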