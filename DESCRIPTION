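Package: mkfop
Title: Network-Informed Transcription-Factor Screening and Platelet Yield
    Analytics for Megakaryocyte Forward Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for megakaryocyte forward-programming studies:
    a differential-expression screen over DNA-binding genes with
    histone-removal curation, interaction-network degree scoring with
    fold-change exclusion rules and rank-sum prioritization of
    transcription-factor cocktail candidates, a whole-transcriptome
    comparison stack (informative-probe filtering, quantile normalization,
    Welch differential expression with Benjamini-Hochberg control,
    correlation-distance average-linkage clustering, hypergeometric and
    running-sum gene-set enrichment, principal-coordinate ordination,
    overlap counting), and quantitative platelet assay calculations
    (relative qPCR expression, bead-based absolute counts, exponential
    survival half-life, aggregation and adhesion percentages, thrombus
    incorporation density, transfusion-unit yield projection). Synthetic
    data generators with planted ground truth make every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    limma,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
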