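Package: panelclass
Title: Actionable-Gene Molecular Classification of Gastric Cancer from
    Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Biomarker calling and molecular classification of gastric
    tumors from targeted panel sequencing profiles: tumor mutational
    burden, microsatellite instability, viral (EBV/HPV) positivity and
    gene-level somatic copy-number calls; assignment of TCGA molecular
    subtypes (EBV, MSI, CIN, GS) by a decision tree; data-driven
    derivation of the hypermutation cutoff as the minimum mutation rate
    among MSI-high tumors; co-alteration similarity clustering of
    actionable genes with 1/(c+1) normalization, Ward linkage and
    stability-based model selection; cohort frequency tables and
    cluster-clinicopathology association statistics; and a seeded
    synthetic-cohort generator so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
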