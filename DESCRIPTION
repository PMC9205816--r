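Package: sparsegp
Title: Sparse Testing and Multi-Environment Genomic Prediction for Plant
    Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating sparse-testing strategies in
    multi-environment plant breeding trials with genomic prediction.  Fits
    single- and multi-environment linear mixed models by residual maximum
    likelihood (REML) with factor-analytic genotype-by-environment covariance,
    genomic (GBLUP) or pedigree (PBLUP) relationship matrices and optional
    separable AR1xAR1 spatial residuals; computes best linear unbiased
    estimates (BLUEs), plot-level heritabilities and genetic correlations
    between selection environments.  Provides sparse-testing line-allocation
    designs (non-overlapping and partially overlapping calibration sets),
    Smith-Hazel index selection, predictive-ability and selection-intersection
    accuracy metrics, and a synthetic breeding-data generator for
    end-to-end evaluation of advancement decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
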