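Package: pkdscreen
Title: Enrichment Analysis of Kinase Substrate-Motif Immunoprecipitation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for nominating protein kinase D (PKD)
    substrates from motif-antibody immunoprecipitation proteomics. Provides
    MaxQuant-style proteinGroups ingestion, razor+unique peptide filtering,
    quantile-anchored imputation of left-censored label-free quantification
    (LFQ) intensities, paired log2 ratio computation, two-tier Tukey/IQR
    fence enrichment classification, consensus-motif scanning for the full
    [L/V/I]xRxx[S/T] and partial Rxx[S/T] PKD motifs, two-screen comparison
    with known-phosphosite cross-referencing, and a synthetic-data generator
    with recorded ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
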