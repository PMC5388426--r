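Package: netfidelity
Title: Transcription Fidelity Analysis of Nascent-RNA 3' Ends from NET-seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Measures transcription misincorporation from NET-seq data, in
    which the sequenced 3' end of each short read is the 3' terminus of a
    nascent RNA still held by RNA polymerase. Provides read-level quality
    control, a unique seed-anchored ungapped aligner with a k-mer
    uniqueness audit, strain-variant masking, per-position total and
    specific (12-class) mismatch rates counted from the 3' end,
    misincorporation hotspot calling with strand-aware sequence-context
    matrices, region-stratified rates per 100 kb, and an analytic model
    that partitions observed mismatches into true misincorporations versus
    reverse-transcription, PCR and sequencing errors. A fully
    ground-truthed synthetic NET-seq generator exercises the pipeline end
    to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    data.table,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
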