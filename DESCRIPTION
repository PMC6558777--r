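Package: startseq
Title: Transcription Start Site Refinement and Pol II Pausing Analysis
    from Start-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of short 5'-capped RNA (Start-seq) sequencing data as
    stranded aligned intervals: strand-specific single-nucleotide 5'- and
    3'-end coverage, base-pair refinement of annotated gene transcription
    start sites with noise and distance filters, calling of divergent and
    convergent antisense initiation around promoters, quantification of
    promoter-proximal RNA polymerase II pausing (pausing index, 3'-end
    metaprofiles, initiation-anchored RNA-length analysis), initiator-motif
    sequence context and information content, and discovery of non-genic
    bidirectional initiation elements. Includes a fully specified synthetic
    data generator with ground truth so every stage is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
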