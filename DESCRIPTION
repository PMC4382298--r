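Package: crsignature
Title: Cross-Tissue Gene-Set Signatures of Caloric Restriction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies tissue-independent transcriptional signatures of
    caloric restriction from multi-study expression data. Computes
    parametric gene-set enrichment (PAGE) Z-scores per study, applies
    gene-set size and ontology-depth filters, detects a cross-study
    consensus signature via term-wise one-sample t-tests with
    Benjamini-Hochberg correction and a median Z-score filter, and
    quantifies conservation of the signature between study groups by
    Spearman concordance under four resampling schemes, including
    Gaussian null models that account for the correlation induced by
    overlapping gene sets. A synthetic-data module generates multi-study
    expression matrices and overlapping gene-set collections with known
    embedded signal for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
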