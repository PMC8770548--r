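Package: iciscape
Title: Immune Cell Infiltration Landscape Analysis for Tumor Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for characterizing the immune cell infiltration (ICI)
    landscape of a tumor cohort from bulk expression data: support-vector
    regression deconvolution against an LM22-like signature matrix, ssGSEA
    stromal/immune scoring, resampled consensus clustering of infiltration
    profiles, moderated-t differential expression and ICI gene signatures,
    a PCA-based per-sample ICI score dichotomized by a maximally selected
    log-rank cutpoint, Kaplan-Meier and time-dependent ROC survival analysis,
    tumor mutational burden association, preranked gene set enrichment, and
    expression-based drug-sensitivity prediction. Includes a synthetic-cohort
    generator that plants cell-type mixtures, expression subtypes, survival
    hazards, batch effects, and score-coupled mutation counts so the whole
    pipeline is testable without access to restricted cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    survival,
    e1071,
    randomForest,
    glmnet,
    sva,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    pracma,
    withr
Config/testthat/edition: 3
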