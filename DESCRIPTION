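Package: silicastage
Title: Multimodal Staging of Engineered-Stone Silicosis from Chest
    Radiographs and Routine Blood Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies simple silicosis versus progressive massive
    fibrosis by fusing chest-radiograph features with routine blood
    biomarkers. Provides lung-field cropping and normalization of
    radiographs, frozen-backbone feature extraction with global average
    pooling, a fold-fitted standardize/PLS-DA/standardize latent
    transform, construction of an inflammation-marker panel (NLR, PLR,
    LMR, SII, SIRI, AISI) with a missingness exclusion filter, early,
    late and hybrid fusion with AUC-proportional decision weights,
    patient-aware stratified group cross-validation with nested
    grid-search tuning, exact Wilcoxon signed-rank model comparison, and
    a synthetic-cohort generator so every stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    ranger,
    xgboost,
    png,
    tiff,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    optparse
Config/testthat/edition: 3
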