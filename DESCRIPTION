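Package: srnalink
Title: Linking Sperm Small RNAs to Transposable Elements and Embryonic Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream integration toolkit for small-RNA, transposable-element
    (TE) and differential-expression results. Implements piRNA seed-region
    complementarity matching against TE reference sequences with family/class
    summaries, a five-step differential-gene/differential-TE overlap pipeline
    with hypergeometric enrichment of TE activity in genic regions and a
    chromosome-wide layout, and seed-based miRNA 3'UTR target identification
    with Fisher-exact enrichment of differentially expressed genes among
    targets. Ships exact log-space combinatorial statistics, strict readers and
    writers for the standard formats involved (FASTA, GTF in Ensembl and
    RepeatMasker/TEtranscripts dialects, DESeq2-style results tables,
    chrom.sizes), and a deterministic seeded simulator that emits every input
    format with planted overlap, enrichment and seed-site structure so all
    pipelines are testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
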