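Package: methexpress
Title: Differential DNA Methylation and Expression Analysis for Plant
    Whole-Genome Bisulfite and RNA-Seq Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An organ-resolved pipeline for two-condition plant epigenomics
    experiments: strand-resolved classification of every cytosine into the
    CG, CHG and CHH sequence contexts; per-sample methylation-level
    summaries with a replicate-aware coverage gate; bisulfite conversion
    efficiency estimated from the unmethylated chloroplast; site-level
    differential methylation (DmCs) by pooled-count Fisher exact tests with
    Benjamini-Hochberg control; fixed-window differentially methylated
    region (DMR) calling with a one-window joining rule; gene-structure
    annotation (2 kb upstream, gene body, 2 kb downstream) and metagene
    methylation profiles; negative-binomial differential expression with
    CPM gating and TMM normalization; and per-gene integration of
    methylation and expression changes with trend classification, gene-set
    overlaps and correlation summaries. A synthetic-data module generates
    genomes, methylomes and count matrices with planted ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
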