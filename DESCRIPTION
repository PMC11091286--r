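Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: reading and harmonizing summary data to a common
    effect allele, instrument selection (genome-wide significance, LD
    clumping, F-statistic screening, blocklist exclusion), causal-effect
    estimation by inverse-variance weighting, MR-Egger, weighted median,
    weighted mode and multivariable IVW, sensitivity diagnostics
    (Cochran's Q, Egger intercept, MR-PRESSO outlier resampling,
    leave-one-out, reverse MR), and two-step MR mediation with
    product-of-coefficients indirect effects and delta-method standard
    errors. Includes a deterministic generator of synthetic two-sample
    GWAS summary statistics with known causal structure for calibration
    and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
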