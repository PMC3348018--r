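Package: swcnv
Title: Copy Number Variant Detection and Inspection from Array CGH and
    Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless toolkit for detecting and inspecting copy number
    variants. Segments array-CGH log2-ratio profiles with a
    Smith-Waterman-style maximum-scoring-island dynamic program using a
    median-absolute-deviation threshold and a minimum island block
    length, flags spurious segments with programmatic quality-control
    statistics, classifies detected segments as known or novel against
    DGV-style and dbSNP-style annotation tables, and computes per-locus
    read depth, nucleotide frequencies, frequency-threshold SNP calls,
    read-depth deletion candidates and between-sample SNP differences
    from BAM alignments. Includes deterministic simulators for aCGH
    profiles and sequence reads with machine-readable ground truth, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
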