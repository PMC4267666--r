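Package: panelomics
Title: Integrative Genome, Transcriptome and Epigenome Analysis of
    Cancer Cell-Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for multi-omics characterisation of a panel
    of cancer cell lines: somatic variant screening against population
    databases with COSMIC rescue and genomic-category burden accounting,
    window-based copy-number gain/loss/amplification calling, discordant
    read-pair rearrangement detection with reference/supporting-tag
    filtering, PPM/RPKM expression quantification with fold-change
    differential calling, bisulfite methylation-rate estimation with
    conversion-rate quality control and CpG island/shore summaries,
    ChIP-seq promoter and enhancer association with differential chromatin
    marks and mark-mark correlation, and cross-layer integration into
    regulatory-mutation overlap tables, per-gene multi-omics status and
    hallmarks-of-cancer aberration scores. Includes a seeded synthetic-panel
    generator with recorded ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
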