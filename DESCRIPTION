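Package: medipdmr
Title: Window-Based Differential DNA Methylation Analysis for MeDIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide differential DNA methylation region (DMR) analysis
    for MeDIP-seq read data. Tiles a reference genome into fixed windows,
    counts PCR-deduplicated reads per window and sample, normalizes library
    sizes by the trimmed mean of M-values (TMM), estimates a common
    negative-binomial dispersion by conditional maximum likelihood, tests
    each window with a two-group negative-binomial conditional exact test,
    and calls DMRs by threshold seeding with iterative edge extension.
    Called regions are annotated with CpG density from the reference and
    with genes within a configurable distance; DMR sets can be compared by
    genomic overlap (Venn and relaxed-threshold extended overlap) and
    visualized by principal component analysis of per-window RPKM. A
    negative-binomial simulator with spiked differential regions provides
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
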