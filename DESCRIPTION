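Package: imprintvc
Title: Variance Components for Genomic Imprinting and Maternal Effects in Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parent-of-origin variance-component analysis of pedigreed
    populations. Builds additive and gametic relationship matrices from
    individual/sire/dam records, fits a ladder of REML mixed models (a
    Mendelian gametic model, maternal environmental and maternal genetic
    extensions, and an imprinting model with two correlated parental gametic
    effects), tests variance components with one-sided restricted
    likelihood-ratio tests under plain and mixture chi-square nulls, computes
    incremental Wald F tables for fixed effects, derives heritabilities and
    maternal-variance ratios with delta-method standard errors, and fits a
    logit threshold (penalized quasi-likelihood) counterpart for binary
    traits. Includes a gene-dropping simulator that generates pedigrees and
    phenotypes with the exact gametic covariance structure the models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
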