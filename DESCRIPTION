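Package: scBilinear
Title: Poisson Bilinear Models for Single-Cell Count Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Model-based dimensionality reduction for single-cell RNA-seq
    UMI count matrices using a Poisson generalized bilinear model with gene
    and cell intercepts and a low-rank log-scale interaction. The model is
    fit by an iteratively reweighted singular value decomposition with
    nuclear-norm soft thresholding, scales to large numbers of cells by
    subsampling and per-cell GLM projection, and quantifies uncertainty in
    the latent cell scores via block Fisher-information standard errors.
    Score uncertainty is propagated to cluster assessment through a
    resampling-based cluster cohesion index with a null significance
    threshold. Includes simulators for benchmark data, count splitting for
    out-of-sample evaluation, subspace-distance metrics, and standard
    transformation-plus-PCA baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    mclust,
    MASS,
    jsonlite,
    withr
Suggests:
    RANN,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SingleCell, DimensionReduction, Clustering, Software
RoxygenNote: 7.3.3
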