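Package: clonalpop
Title: Clonal Population Genomics and Abundance Estimation for
    Parthenogenetic Crayfish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for nearly monoclonal, triploid crayfish
    populations. Reads and filters VCF variant calls against a clonal
    reference, recodes triploid genotypes to alternative-allele dosage
    (0-3), partitions single-nucleotide variant sharing across samples
    and groups, builds neighbor-joining distance trees and principal
    component analyses of the dosage matrix, and scans windowed variant
    allele frequencies at reference-heterozygous positions for loss of
    heterozygosity.  A companion ecological toolkit estimates population
    size from multi-day mark-recapture trap surveys (Schnabel estimator
    with asymptotic saturation regression, bathymetry-stratified
    extrapolation and bootstrap standard errors) and simulates population
    growth under exponential, logistic and strong-Allee models together
    with the accumulation of genetic variability.  A synthetic-data
    generator produces clonal triploid genotype truth sets, VCFs with
    binomial read sampling, and closed-population trap surveys so that
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phangorn,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Config/testthat/edition: 3
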