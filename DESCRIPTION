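Package: spliceorder
Title: Co-Transcriptional Splicing Order and Multi-Step Intron Removal
    from Capture Pre-mRNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of intron removal order and multi-step splicing in
    long pre-mRNA transcripts from targeted (capture) paired-end
    sequencing of nuclear RNA. Classifies read pairs into pre-,
    intermediate- and post-splicing phases, infers relative intron
    removal speed from normalized median intron coverage, computes
    per-intron splice-ratios from junction/intron read pairs, derives
    exon blocks, discovers and classifies multi-step splicing events
    (5' and 3' recursive, intermezzo, nested) from gapped alignments,
    and characterizes splice-site motifs. Includes a synthetic
    co-transcriptional splicing read generator with full truth tables
    so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    tools,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
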