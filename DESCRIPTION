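Package: mrbattery
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization using GWAS summary
    statistics: harmonization of exposure and outcome association tables
    (palindromic-allele and imputation-quality filters, effect-allele
    alignment), greedy LD-based selection of independent genome-wide
    significant instruments, four causal estimators (inverse-variance
    weighted regression with and without pleiotropic-SNP exclusion, the
    interpolated weighted median, and MR-Egger regression with its intercept
    test for directional pleiotropy), liability-scale variance explained,
    and an orchestrated multi-trait bidirectional test battery with
    Bonferroni correction. A summary-level GWAS simulator with a ground-truth
    ledger supports calibration and power checks without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
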