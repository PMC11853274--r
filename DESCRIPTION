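Package: spliceDispersion
Title: Dispersion Profiles of Hexamer Subsets Around Acceptor Splice Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies canonical (GT-AG) acceptor splice sites into splicing
    modes (common, constitutive, alternative, with normal/exonic/intronic
    sub-modes) from a genome FASTA and GTF annotation, extracts aligned 100-bp
    acceptor windows, partitions the 6-mer vocabulary into XY1/XY0 subsets by
    dinucleotide containment, computes positional dispersion profiles
    (the ratio of a subset's frequency standard deviation to that of the full
    vocabulary), and compares splicing modes region by region with paired
    t-tests under Benjamini-Hochberg false discovery rate control. A seeded
    synthetic-sequence generator with motif injection makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
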