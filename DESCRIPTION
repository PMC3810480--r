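Package: lrlmm
Title: Low-Rank Linear Mixed Models for Population Structure and Kinship
    Correction in GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spectral fitting of linear mixed models (LMM) for genome-wide
    association studies, with an effective-degrees-of-freedom statistic that
    measures the complexity of the correction for population structure and
    kinship, and a low-rank linear mixed model (LRLMM) that learns the
    dimensionality of that correction by ordering principal components of a
    genetic similarity matrix and selecting the rank with an information
    criterion (AIC, BIC, GCV or the log-likelihood). Includes readers for
    PLINK additive-dosage and plain TSV genotype formats, genetic
    relationship matrix construction, Balding-Nichols structured-population
    simulators, per-marker association scans with genomic-control
    diagnostics, and an FDR/power evaluation harness with positional
    clustering of false positives.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
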