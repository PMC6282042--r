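Package: semscan
Title: Latent-Variable Structural Equation Models and Single-Step GBLUP
    Genome Scans for Correlated Quality Traits
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds latent phenotypes (e.g. carcass quality and meat
    quality in beef cattle) from observed indicator traits with a
    confirmatory structural equation model, runs single-step genomic BLUP
    (ssGBLUP) whole-genome scans on the latent factor scores, partitions
    additive genetic variance into 20-SNP windows, and classifies genomic
    regions into direct, pleiotropic and indirect effects by comparing
    scans with and without conditioning on the upstream latent variable.
    Includes pedigree/genomic/combined relationship matrix construction
    with SNP quality control, EM-REML variance components, back-solving
    of SNP effects from breeding values, and a fully synthetic data
    generator (pedigree, gene-dropped genotypes, factor-structured
    phenotypes with planted QTL) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
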