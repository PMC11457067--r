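Package: sparsetest
Title: Multi-Site, Multi-Trait Genomic Prediction with Sparse Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction tools for multi-environment perennial crop
    trials built around spaced-plant biomass evaluation of switchgrass
    (Panicum virgatum). Provides marker quality control and the VanRaden
    realized relationship matrix; additive main effects and multiplicative
    interaction (AMMI) decomposition of genotype-by-environment structure;
    multi-trait GBLUP fitted by EM-REML with genetic correlations and
    Cullis-style heritability; a Bayesian multivariate Gaussian sampler with
    Kronecker-structured genetic covariance across sites and yield-surrogate
    traits; sparse-testing cross-validation (CV1/CV2 and resource-limited
    surrogate scenarios); and a synthetic-data generator emulating a
    structured diversity panel evaluated across a latitudinal site gradient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
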