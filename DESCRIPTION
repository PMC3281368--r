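Package: its2repeats
Title: Tandem Repeat Detection, Grouping and Phylogenetics for rDNA Spacer Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects long (>30 bp) tandem repeats in ribosomal DNA internal
    transcribed spacer sequences by dot-plot self-comparison, delimits repeat
    units with conserved terminal motifs, clusters units into groups by
    Jukes-Cantor distance with bootstrap-support overrides, and builds
    neighbor-joining trees of repeat units and of repeat-masked spacers.
    Includes a seeded synthetic-data generator that plants repeat arrays of
    known group structure so every pipeline stage can be validated by
    parameter recovery, modelled on the repeat architecture of the ITS2
    region in the Anopheles barbirostris species complex.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
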