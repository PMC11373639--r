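Package: blupberry
Title: Longitudinal Genomic Prediction for Autotetraploid Postharvest Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal genomic analysis of postharvest fruit
    quality traits in autotetraploid breeding populations such as southern
    highbush blueberry. Builds the tetrasomic VanRaden genomic relationship
    matrix from allele dosages, fits longitudinal GBLUP mixed models by REML
    with unstructured genetic and residual covariances across storage time
    points, estimates per-time-point narrow-sense heritability and genetic
    correlations, quantifies crossover genotype-by-time interactions (the psi
    statistic), and runs CV1/CV2 genomic prediction cross-validation schemes.
    Includes a synthetic tetraploid population generator with known truth for
    validation, and derived-trait utilities (water loss percentage, pedicel
    scar coefficient, delta traits).
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
    withr
Config/testthat/edition: 3
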