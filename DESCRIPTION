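Package: sncsig
Title: Read-Pair Overlap Signatures for Small RNA Pathway Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects Dicer-processed endo-siRNA and ping-pong piRNA
    signatures in aligned small-RNA libraries from the distribution of
    5'-5' overlaps between opposite-strand read pairs, standardized as a
    Z-score profile over overlap groups 4-20 nt. Classifies putative
    siRNA and piRNA read pairs with coverage, log-ratio and miRNA-region
    filters, builds RPM length/class expression profiles, assigns miRNA
    genes to known families by local alignment plus identical seed and
    clusters the remainder into novel families, and compares root-to-tip
    branch rates between labelled tip groups of a phylogeny. Includes a
    seeded simulator of small-RNA libraries (miRNA hairpins, siRNA
    duplexes, ping-pong pairs, background) with ground-truth tables for
    validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    ape,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
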