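Package: ucrmotifs
Title: Cis-Regulatory Motif Discovery and Co-Regulation Networks in
    Upstream Control Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers, scores and interprets cis-regulatory DNA motifs in
    upstream control regions (UCRs) of co-expressed gene sets. Builds
    3 kb, ORF-trimmed UCR databases from genome sequence and annotation;
    finds candidate motifs with a seeded ZOOPS Gibbs sampler; evaluates
    them with group-specificity (Church, hypergeometric), ROC-AUC and
    binomial enrichment statistics behind a two-stage filter cascade;
    matches retained motifs to known transcription-factor binding sites
    in TRANSFAC-format libraries by position-specific scoring matrix
    (PSSM) column identity; scans for IUPAC consensus sites such as the
    FTZ-F1 element; and assembles bipartite motif-gene co-regulation
    networks over gene categories. Includes a fully seeded synthetic
    genome and promoter simulator with planted motifs for benchmarking,
    plus small reporting utilities (differential-expression summaries,
    cross-platform concordance, qPCR efficiency, cuticular-protein
    sequence features).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    readr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
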