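Package: cannabismr
Title: Two-Sample Mendelian Randomization of Cannabis Use and
    Atherosclerotic Cardiovascular Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a complete two-sample Mendelian randomization (MR)
    workflow for assessing whether liability to cannabis use causally affects
    coronary artery disease and ischemic stroke: reading and harmonizing GWAS
    summary statistics, instrument filtering (discordant variants, palindromic
    ambiguity, significance thresholds), per-SNP Wald ratios with delta-method
    standard errors, fixed- and random-effects inverse-variance-weighted
    pooling, MR-Egger with bootstrap standard errors and SIMEX correction,
    weighted-median estimation, Steiger directionality filtering, multivariable
    MR adjusting for tobacco, instrument-strength and power diagnostics,
    DerSimonian-Laird random-effects meta-analysis of observational studies
    with funnel-asymmetry testing, and conversion of per-log-unit causal
    estimates to population-scale ever- versus never-user odds ratios. A
    synthetic two-sample summary-statistics generator reproduces the
    statistical structure the analysis assumes so every stage is testable
    without external downloads.
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
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
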