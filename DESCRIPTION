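Package: sweepscan
Title: Multi-Population Selective-Sweep Scans from Phased SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects breed- or population-specific selective sweeps from
    phased, bi-allelic SNP genotypes. Implements windowed Weir-Cockerham
    F_ST, a four-population branch statistic (PBS4) built on log-transformed
    F_ST branch lengths, cross-population extended haplotype homozygosity
    (XP-EHH) with genome-wide normalization and per-window maxima,
    nucleotide diversity and Tajima's D validation scans, empirical top-
    quantile outlier calling with gene annotation, population-structure
    support analyses (p-distance neighbor-joining tree, GRM PCA, f3 test),
    SNP quality-control filters, and seeded simulators (Balding-Nichols
    genotypes, mosaic-founder haplotypes with a planted sweep, neutral
    coalescent) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    ape,
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
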