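Package: surflesion
Title: Surface-Based Lesion Detection with AFROC Evaluation Against a
    Random-Guessing Null
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vertex-wise detection of focal cortical lesions on a symmetric
    two-hemisphere template mesh, evaluated with alternative free-response ROC
    (AFROC) methodology against a Monte-Carlo random-guessing null hypothesis.
    Provides a synthetic-cohort generator for surface-based morphometry
    measures with covariate structure and implanted lesions, feature
    augmentation (two smoothing scales, difference-of-Gaussians, hemispheric
    asymmetry) with two-stage z-scoring, single-subject-versus-controls
    general linear models, unsupervised novelty detection (robust Mahalanobis
    distance, isolation forest) and a supervised random-forest comparator,
    cluster/centroid-based AFROC curves, and the closed-form guessing model
    TPF = 1 - (1 - FPF)^phi with AUC = phi/(phi + 1) together with
    finite-cohort Monte-Carlo null distributions and permutation-style
    p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Matrix,
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
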