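Package: cernet
Title: Correlation-Based ceRNA Network Construction and Query Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds competitive-endogenous-RNA (ceRNA) networks from
    expression matrices of mRNAs, lncRNAs and miRNAs: expression filtering,
    Pearson correlation tables with p-values, sign-constrained
    lncRNA-miRNA-mRNA triangle-motif enumeration gated by miRNA-target
    interaction evidence, strand-opposed (sense-antisense) overlap
    detection and classification of gene pairs, transcription-factor
    target discovery gated by ChIP-seq binding evidence, and expression
    summaries grouped by clinical parameters. Ships seeded synthetic-data
    generators with planted ground truth so the whole pipeline is testable
    without external downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
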