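Package: srnapipe
Title: Small RNA Discovery from 454 and SOLiD Colorspace Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering and classifying
    endogenous small RNAs in compact genomes from mixed sequencing
    libraries: adapter-flanked 454-style reads and 35-cycle SOLiD
    colorspace reads. Provides colorspace decoding and alignment-based
    read trimming, substring clustering of unique tags, ribosomal/tRNA
    degradation filtering, strand-aware genome coverage binning, miRNA
    hairpin prediction with structural filters (loop length, bulge size,
    minimum free energy), repeat-associated and natural-antisense siRNA
    classification, plant- and animal-style miRNA target prediction with
    GO enrichment ratios, and a synthetic-data generator with planted
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
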