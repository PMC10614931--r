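Package: twasvc
Title: Variance Control for Polygenicity-Driven Inflation in TWAS and xWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transcriptome-wide association studies (TWAS) and related xWAS
    methods test genetically predicted molecular mediators against a complex
    target trait. When the target trait is highly polygenic, the standard
    Z-score is inflated in proportion to the GWAS sample size N and the trait
    heritability h2, with a per-mediator inflation slope Phi determined by the
    prediction weights and the LD structure. twasvc simulates genotypes,
    mediator prediction models and null/polygenic/alternative target traits;
    computes Phi both in closed form (an LD quadratic-form ratio) and
    empirically (regression of average squared Z-scores on N*h2 over a
    simulation grid); applies the per-mediator variance-control correction
    z / sqrt(1 + N*h2*Phi); and provides calibration diagnostics (Z-score
    sample variance, QQ coordinates, uniformity tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    yaml,
    vcfR
Config/testthat/edition: 3
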