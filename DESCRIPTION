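Package: uridylome
Title: Calling Non-Templated 3' Oligo(U) Tails in CLIP-Seq Reads
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale pipeline for analysing CLIP-seq libraries of
    3'-uridylated RNAs ("uridylome" profiling). Implements two-pass read
    mapping with 3' oligo(T) trimming, identification of non-templated 3'
    tails against a reference genome, priority-ordered functional annotation
    of target RNAs, detection of hybrid reads arising from intramolecular
    RNase T1 ligation, and positional summaries (scaled gene-body coverage,
    tail-length histograms, TSS-anchored metagene profiles). Includes a
    seeded CLIP-read simulator with machine-readable ground truth so that
    every stage of the analysis is verifiable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
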