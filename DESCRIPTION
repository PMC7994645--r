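Package: emdrank
Title: Drug Ranking from Omics Profiles via Empirical Markers of Drug Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts and ranks the anti-proliferative efficacy (AAC, area above
    the dose-response curve) of drug panels within individual cancer samples from
    phosphoproteomics, proteomics or transcriptomics abundance matrices. For each
    drug, empirical markers of drug response (EMDRs) are discovered by fold-pair
    resampling of a median-AAC sensitive/resistant split with empirical-Bayes
    moderated t-statistics; marker sets are collapsed into an internally
    normalized distance metric D (difference of median and third-quartile
    statistics between sensitivity- and resistance-marker distributions); an
    ensemble of regression models trained on Spearman-selected D features
    predicts responses on held-out samples. Includes ranking evaluation metrics,
    marker-set enrichment and drug-drug similarity scoring, and a synthetic
    cell-line panel generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    caret,
    randomForest,
    xgboost,
    glmnet,
    e1071,
    nnet,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
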