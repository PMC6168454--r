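Package: polsmm
Title: Pace-of-Life Syndromes via Multivariate REML Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pace-of-life-syndrome (POLS) analyses of repeated
    phenotypic measurements: extraction of standard metabolic rate from
    intermittent-flow respirometry traces via closed-phase slope filtering
    and a two-component normal mixture, a restricted-maximum-likelihood
    engine for univariate and multivariate individual-random-intercept
    mixed models with constrainable among-individual and residual
    covariance structures, adjusted repeatability with boundary-corrected
    chi-square mixture likelihood-ratio tests, among- versus
    within-individual covariance decomposition, cross-population tests of
    covariance-structure equality, and a synthetic-data generator that
    emulates a two-population repeated-measures study design with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mclust,
    emmeans,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
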