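Package: hlarisk
Title: Carrier-Based HLA Association, Screening and Meta-Analysis for
    Drug-Hypersensitivity Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case-control pharmacogenomic studies of HLA class I
    and II alleles and cutaneous adverse drug reactions. Implements
    carrier-rate 2x2 association scans with Woolf confidence intervals and
    per-locus Bonferroni correction, prevalence-adjusted screening metrics
    (sensitivity, specificity, PPV, NPV, number needed to test), two-locus
    interaction decomposition on multiplicative and additive scales with a
    grouped logistic product-term model, Mantel-Haenszel fixed-effect and
    DerSimonian-Laird random-effects meta-analysis of per-study carrier
    tables with Cochran's Q and I-squared, and a Hardy-Weinberg synthetic
    cohort generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
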