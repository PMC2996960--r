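Package: rnpscan
Title: Detection of RNase P RNA (rnpB) Genes by Descriptor Filtering and
    Covariance-Model Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Finds RNase P RNA (rnpB) genes in genomic and metagenomic
    nucleotide sequences with a two-stage cascade: a fast secondary-structure
    descriptor matcher acts as a subfamily-specific filter, and a simplified
    covariance model (profile stochastic context-free grammar) validates
    candidates and refines gene boundaries.  E-values are calibrated on
    dinucleotide-shuffled decoys under a Gumbel null.  Includes tools to build
    descriptor and covariance models from structural alignments, post-scan
    analyses (deduplication, subfamily tallies, GC content, nearest-homolog
    assignment, gene-size/genome-size correlation), and a synthetic-genome
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
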