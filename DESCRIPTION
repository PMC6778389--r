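Package: capclust
Title: Tag Clustering and Enhancer Prediction from 5'-End Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of 5'-end transcriptome data (CAGE, PRO-Cap and related
    assays) starting from per-basepair, per-strand counts of tag 5' ends
    (CTSSs). Imports stranded CTSS tracks from BigWig or bedGraph files,
    normalizes to tags-per-million and pools signal across samples, calls
    unidirectional tag clusters (TSS candidates) by slice-reduce clustering and
    bidirectional clusters (enhancer candidates) by a Bhattacharyya-coefficient
    balance score, annotates clusters hierarchically against transcript models,
    computes promoter shape statistics (interquantile width and entropy),
    builds gene-level and alternative-TSS expression matrices, predicts
    TSS-enhancer co-expression links with FDR control, and merges enhancers
    into stretches. Includes a synthetic CTSS data generator with ground truth
    for end-to-end validation. All user-facing functions take and return tidy
    data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
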