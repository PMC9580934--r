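Package: dmdir
Title: Model Directionality in Cell-Type-Specific Differential Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation benchmark for studying how the assumed model
    directionality (methylation as the dependent variable, X|Y, versus the
    phenotype as the dependent variable, Y|X) affects cell-type-level
    differential methylation calling from bulk tissue data. Provides a
    directional generator of synthetic bulk methylation cohorts with known
    cell-type-level effects, an interaction-term regression test
    (CellDMC-style, structurally X|Y), a latent component-mixture model of
    cell-type-specific methylation that can test associations in either
    direction, and evaluation tools: sensitivity/specificity/precision
    scoring against the simulated ground truth, cross-cohort validation-rate
    curves, and a method-consistency diagnostic for the likely directionality
    of real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
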