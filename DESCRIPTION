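Package: tdmr
Title: Association of Tissue-Specific Differentially Methylated Regions
    with Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links tissue-specific differentially methylated regions
    (T-DMRs) to genes and classifies each pair as positively or negatively
    correlated from the signs of the between-tissue methylation difference
    and the log2 expression difference. Provides permutation (shuffle)
    Z-score tests for the coherence of genes carrying multiple T-DMRs,
    genomic-context characterization (feature categories, DNase
    hypersensitive site overlap enrichment, conservation ECDFs, CpG
    observed/expected ratio), hypergeometric gene-set enrichment with
    Bonferroni or Benjamini-Hochberg correction, and 6-mer motif discovery
    against length-matched random backgrounds with binomial tests. A
    synthetic-data generator with planted structure makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
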