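Package: aneuQTL
Title: Genetic Association Testing at Aneuploid Triploid Loci in Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical model for detecting genetic control of quantitative
    cancer phenotypes at aneuploid (triploid) loci. Provides estimation of
    allele frequencies and Hardy-Weinberg disequilibrium coefficients from
    triploid genotype counts, a parent-of-origin finite normal-mixture model
    fitted by the EM algorithm to estimate configuration means and
    chromosome-duplication rates, decomposition of configuration means into
    additive, dominance, imprinting and interaction effects, likelihood-ratio
    hypothesis tests for each effect, and a Monte-Carlo simulation harness
    for parameter-recovery, power and false-positive studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
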