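Package: caretakeR
Title: Mutation-Race Modelling and Clone-Competition Statistics for
    Ribosomal-Protein-Gene Haploinsufficiency
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for studying haploinsufficient ribosomal
    protein genes (hRPGs) as caretakers of genomic integrity in Drosophila.
    Provides a Monte-Carlo model of random mutation accumulation in a diploid
    genome with an exact dynamic-programming oracle for the probability that
    an hRPG becomes heterozygous before any gene reaches homozygosity;
    genomic interval arithmetic in the FlyBase 1-based inclusive dialect
    (lengths, sequence-change parsing, frameshift calls, BED conversion);
    binned gene-density and intragenic-fraction computations; twin-spot
    clone-area ratio statistics with a two-criterion suppressor-calling rule
    (rank-test ratio increase plus D'Agostino-Pearson normality
    restoration); and synthetic-data generators so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
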