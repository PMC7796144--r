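Package: weasca
Title: Weighted-Effect ASCA for Unbalanced Multifactorial Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: ANOVA-simultaneous component analysis (ASCA) for multivariate
    responses measured under multifactorial experimental designs, including
    the weighted-effect variant (WE-ASCA) for unbalanced designs. Effect
    matrices are estimated through a multivariate general linear model with
    dummy, deviation (sum-to-zero) or weighted-effect coding of the design
    matrix; the classical cell-mean ASCA estimator is provided for
    comparison. Includes type III variance partitioning, permutation tests
    of effect significance, PCA sub-models of effect matrices with
    residual-augmented score plots, effect-removal preprocessing inside
    leave-one-group-out cross-validated PCA-LDA and PLS-DA classification,
    and a synthetic spectra-like data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    ggplot2,
    optparse,
    yaml
Config/testthat/edition: 3
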