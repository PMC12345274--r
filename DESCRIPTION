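Package: grnrewire
Title: Multi-Omics Gene Regulatory Network Construction and Cross-Species
    Rewiring Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds transcription-factor-centred gene regulatory networks by
    integrating ChIP-seq peak calls, RNA-seq differential expression, and
    protein-protein interaction evidence, and compares the resulting networks
    between species through an ortholog map. Implements FPKM filtering and
    quantile normalization, dual-threshold differential expression calling,
    promoter-window peak-to-gene assignment, direct-target classification,
    confidence-filtered PPI backbone construction with guilt-by-association
    expansion, core-subnetwork extraction, ortholog-based target partitioning,
    hypergeometric Gene Ontology over-representation, and exact-mass metabolite
    differential and identification analyses. A synthetic-data module generates
    two-species multi-omics datasets with planted ground truth so every stage
    of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    limma,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
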