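Package: protsig
Title: Circulating Protein Signature Discovery and Prognostic Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering circulating-protein biomarker
    signatures from Olink-style NPX panels and evaluating their prognostic
    value in oncology cohorts. Implements two complementary strategies:
    (1) resampled logistic-LASSO stability selection with per-marker
    proportion scores, nested signature sets and Ridge-based
    discovery/replication evaluation with Youden cutoffs and stratified
    bootstrap confidence intervals; and (2) repeated cross-validated
    median-lambda penalized logistic and (non-negative) Cox risk models with
    linear prediction scores. A full survival-evaluation layer provides ROC
    and time-dependent ROC analysis, Kaplan-Meier and logrank comparisons,
    Cox proportional-hazards summaries, horizon classification and
    median/maximally-selected risk-score cutpoints. A synthetic-cohort
    generator with exported ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
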