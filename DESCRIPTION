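Package: endmate
Title: Transcript Unit Analysis from TSS-PAS Mate-Pair cDNA Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of mate-pair sequence tags derived from the two ends of
    full-length cDNAs, where the 5' tag marks the transcription start site
    (TSS) and the 3' tag marks either the poly(A)-addition site (PAS) or a
    random internal position. Provides end-tag clustering into 500-bp start
    and termination clusters (TSCs/PACs) with ppm expression quantification,
    Poisson significance screening of cluster concentration on the mRNA,
    gene-model association and cis-motif scans, a Poisson independence test
    that identifies mutually preferred TSC-PAC pairings, tissue-specificity
    Z-scores with switching detection, detection of transcript units
    connecting adjacent genes and of candidate fusion transcripts,
    genome-guided assembly of tags into transcript models with an integrity
    score, ChIP fold-density metaprofiles, and a synthetic-data generator
    that reproduces the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
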