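Package: broadHMM
Title: Differential Analysis of Broad Histone Modification Domains with a
    Bivariate Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised segmentation of broad-footprint histone-modification
    ChIP-seq signal (e.g. H3K27me3, H3K9me3) into modified and unmodified
    domains, and probabilistic differential analysis of two samples. Per-bin
    read counts are modelled by a two-component zero-inflated negative
    binomial mixture fitted by EM; the mixture components serve as fixed
    emission densities of a two-state hidden Markov model for single samples.
    For two-sample comparison the four combinations of per-sample states are
    coupled through a Gaussian copula on the probability-integral-transformed
    counts, yielding a four-state HMM that classifies every genomic bin as
    modified in both samples, unmodified in both, or modified in exactly one.
    Includes genome binning from BAM/BED alignments, seeded simulators with
    known ground truth, and BED/GFF3/bedGraph exporters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    mvtnorm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
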