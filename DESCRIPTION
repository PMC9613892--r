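Package: pdstack
Title: Stacked Meta-Prediction of Short-Term Parkinson's Disease
    Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genetically informed prediction of short-term Parkinson's
    disease progression from baseline clinical, imaging and genetic data.
    Implements medication-adjusted progressor labelling from longitudinal
    MDS-UPDRS scores, genotype quality control and polygenic risk scoring,
    Shapley-value feature selection, gradient-boosted subpart-by-horizon
    submodels stacked into a meta-predictor of 12-month MDS-UPDRS Total
    progression, feature-class ablation, trial-enrichment power
    calculations, and a synthetic paired-cohort generator with planted
    effect structure for end-to-end validation without access-controlled
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
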