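Package: circflow
Title: Circular RNA Discovery, Quantification and Characterization from
    RNA-Seq Back-Splice Junction Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained workflow for genome-wide identification and
    characterization of circular RNAs (circRNAs) from rRNA-depleted,
    RNase R-treated RNA-seq data. Implements two independent back-splice
    junction callers (a chimeric split-segment caller and a
    candidate-realignment caller) with per-sample two-caller consensus and
    cross-sample catalog merging; junction classification into exonic,
    intronic and intergenic circRNAs with alternative-circularization
    summaries; junction-read RPM quantification and tissue-pair
    differential expression with Benjamini-Hochberg q-values; Pearson
    co-expression of circRNAs with parental genes and with module
    eigengenes, plus hypergeometric term enrichment; miRNA sponge-site
    scanning with a complementarity penalty score; and convergent/divergent
    primer design with in-silico PCR validation. A synthetic-data module
    generates multi-scaffold genomes, multi-exon gene models, planted
    circRNAs and paired-end reads so the whole pipeline can be exercised
    and validated without external data.
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
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
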