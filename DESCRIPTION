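Package: teburst
Title: Detection and Epigenomic Analysis of LTR Retrotransposon Insertion Bursts from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the aftermath of an LTR retrotransposon
    mobilisation burst from long-read sequencing data. Detects novel
    transposable element insertions from soft-clip and insertion CIGAR
    signatures, reconstructs inserted sequences by anchor-based consensus,
    builds per-sample pseudoreferences with duplicated target-site
    duplications and an invertible coordinate liftover, assigns insertions
    to parental donor copies via diagnostic SNPs in the reverse-transcriptase
    domain, computes CG/CHG/CHH methylation metaplots over element bodies and
    flanks with control subtraction, performs positional and chromatin-state
    enrichment statistics, and classifies transposon-gene transcript events
    (intronization, alternative transcription start/termination). A fully
    deterministic synthetic-data generator with ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
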