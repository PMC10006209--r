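Package: ldsem
Title: Multivariate LD Score Regression and Genomic Structural Equation
    Models for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for multi-trait analysis of genome-wide
    association study (GWAS) summary statistics: harmonization and quality
    control of per-trait association records, effective sample sizes for
    case-control traits, LD score regression estimates of SNP heritability
    and genetic covariance with block-jackknife sampling covariances,
    instrument-based conditioning of one trait on another, and genomic
    structural equation models fitted by diagonally weighted least squares
    with sandwich standard errors, model test statistics, and fit indices.
    Includes a summary-level simulator with known latent factor structure
    so every stage can be validated against ground truth.
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
    optparse
Config/testthat/edition: 3
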