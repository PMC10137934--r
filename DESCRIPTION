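Package: rvburden
Title: Rare-Variant Gene Burden Testing with Cohort Quality Control
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Case-control gene burden analysis for rare putative damaging
    variants in a single gene: sample-level quality control (contamination,
    call missingness, variant-count outliers, KING-robust kinship pruning,
    principal-component ancestry filtering), site-level genotype quality
    filters, consensus missense deleteriousness classification, carrier
    collapsing with exact case-control statistics (two-sided Fisher exact
    test, cross-product odds ratios with Woolf confidence intervals,
    Bonferroni correction), an allele-count mode for public reference
    controls, compound-heterozygote detection, and single-cell expression
    summaries (TPM normalization and cluster dot-plot statistics).  A
    synthetic cohort generator with a ground-truth ledger lets every stage
    be exercised and validated fully offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
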