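Package: adgblup
Title: Additive and Dominance GBLUP for Half-Sib Livestock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction workflow for SNP-genotyped livestock
    populations dominated by paternal half-sib families. Reads and writes
    PLINK 1 binary genotypes, applies marker and sample quality control
    (call rate, exact Hardy-Weinberg test, minor allele frequency, autosome
    restriction), builds VanRaden additive (G) and classical
    dominance-deviation (D) genomic relationship matrices, estimates
    additive, dominance and residual variance components by
    average-information REML with EM fallback and boundary constraints,
    solves BLUP genetic values from the fitted mixed model, and evaluates
    prediction accuracy by repeated k-fold cross-validation. A half-sib
    population simulator with known additive/dominance architecture makes
    the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
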