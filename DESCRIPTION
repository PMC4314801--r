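Package: sweepscan
Title: Genome-Wide Selective Sweep Scans from Phased Two-Population Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic regions under recent positive selection by
    contrasting two populations of phased diploid haplotypes. Implements
    cross-population extended haplotype homozygosity (XP-EHH) with
    genome-wide standardization, a cross-population composite likelihood
    ratio (XP-CLR style) scan over sweep-distorted allele-frequency
    differentiation, sliding-window minor-allele-frequency summaries,
    Tajima's D with a fixed-S coalescent null, distance-binned linkage
    disequilibrium decay, windowed empirical P-value outlier calling with
    SNP-count binning, candidate-gene annotation, and GATK-style hard
    filtering of variant tables. A forward Wright-Fisher simulator of two
    diverged populations with an optional additive selective sweep provides
    reproducible synthetic data bundles for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vcfR,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    pracma,
    withr,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
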