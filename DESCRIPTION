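Package: sslmm
Title: Summary-Statistics Linear Mixed Models for Single-Cell Differential
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fast, memory-light per-gene linear mixed-effects model (LMM)
    fitting for multi-subject single-cell RNA-seq differential expression.
    Model estimation (ML/REML) operates entirely on a low-dimensional
    sufficient reduction of the data (X'X, X'Y, Z'X, Z'Y, Z'Z and per-gene
    y'y), so fitting cost is independent of the number of cells. Variance
    components are estimated in a reparameterization that allows negative
    values, moving the null off the boundary so that t/z statistics and the
    likelihood ratio test have their usual asymptotic distributions. Includes
    design-matrix construction with cell-type-nested condition contrasts, a
    reference-based negative-binomial scRNA-seq simulator with
    method-of-moments dispersion estimation, QC filtering, ROC/QQ evaluation
    utilities, and an end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
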