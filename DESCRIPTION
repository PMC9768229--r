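Package: pirnakit
Title: Identification, Characterization and Differential Expression of
    PIWI-Interacting RNAs from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a testis small RNA-seq piRNA
    profiling workflow: raw-read quality filtering and adapter trimming with
    exact per-category accounting, collapse of reads to unique sequence tags,
    removal of known small RNA classes against user-supplied reference sets,
    candidate piRNA calling by the 1U/10A rule, sequence characterization
    (length distributions, positional base composition, ping-pong 5'-overlap
    signature), genomic and transposon origin assignment, sliding-window piRNA
    cluster detection with strand-specificity and 5'U statistics, and TPM-based
    negative-binomial differential expression screening. Ships a ground-truth
    synthetic data generator (toy genome, annotations, contaminant references
    and FASTQ libraries) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
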