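Package: medmr
Title: Two-Sample Two-Step Mediation Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for two-sample, two-step mediation Mendelian
    randomization from GWAS summary statistics: instrument selection
    (significance thresholding, LD clumping, allele harmonization with
    palindrome handling, F-statistic and Steiger directionality filters,
    blocklist and Bonferroni outcome exclusion), a suite of causal
    estimators and diagnostics (Wald ratio, fixed- and random-effects
    inverse-variance weighting, MR-Egger with intercept test, weighted
    median, robust adjusted profile score, Cochran's Q, MR-PRESSO,
    leave-one-out, Steiger direction test, statistical power),
    product-of-coefficients mediation screening with mediation proportions,
    and hypergeometric over-representation analysis of mediator proteins
    against GMT gene sets. A synthetic GWAS summary-statistics generator
    with known structural ground truth (exposure, protein mediators,
    outcome; pleiotropy, reverse causation, planted outliers) makes every
    stage verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
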