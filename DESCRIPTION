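Package: scSemiLab
Title: Semi-Supervised Cell-Type Annotation for Single-Cell RNA-Seq via
    Cluster-Derived Pseudo-Labels
Version: 0.1.0
Authors@R:
    person("scSemiLab", "Developers", email = "scsemilab@example.org",
           role = c("aut", "cre"))
Description: Annotates single-cell RNA-seq data from a small labeled subset
    plus a large pool of unlabeled cells. A compact multi-layer perceptron is
    pretrained on unlabeled cells with a normalized temperature-scaled
    contrastive (NT-Xent) loss over weakly (Gaussian-noise) and strongly
    (random-masking) augmented views, warmed up on the labeled cells, and then
    refined with pseudo-labels obtained by class-center-seeded spherical
    K-means on an intermediate embedding. A learned confidence estimator
    weights each pseudo-label inside a consistency-regularization loss, with
    the annotator and estimator trained in alternation. Includes the standard
    scRNA-seq preprocessing pipeline (cell/gene filtering, library-size
    normalization, log1p, highly-variable-gene selection, unit-variance
    scaling), a negative-binomial synthetic-data generator with dropout for
    fully offline benchmarking, stratified cross-validation and
    label-fraction experiment designs, and readers/writers for dense
    CSV/TSV and 10X-style MatrixMarket matrices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
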