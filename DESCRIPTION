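Package: dmlmm
Title: Deep Mixtures of Linear Mixed Models for Unbalanced Longitudinal Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits linear mixed models for unbalanced longitudinal data in which
    subject-specific basis coefficients carry a deep mixture-of-factor-analyzers
    prior, using structured mean-field variational inference with natural-gradient
    stochastic updates. The collapsed Gaussian-mixture representation gives
    closed-form marginal and conditional predictive distributions, implicit
    clustering of subjects, credible intervals and threshold-risk calculations,
    and a prior-data-conflict diagnostic based on a Kullback-Leibler tail
    probability. Includes Legendre-polynomial and seasonal B-spline design
    matrices, simulation generators for benchmark data-generating processes, and
    text-based model serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, splines
Suggests: testthat (>= 3.0.0), withr, deSolve, optparse
Config/testthat/edition: 3
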