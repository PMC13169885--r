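Package: voicemark
Title: Speech and Language Biomarkers for Mood Disorder Group Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for differentiating bipolar disorder from
    major depressive disorder using speech and language biomarkers extracted
    from short monologue recordings and their transcripts. Provides a
    synthetic cohort generator with known ground truth, acoustic feature
    extraction (dB-gated pause detection with minimum/maximum duration rules,
    peak and RMS-derived amplitude statistics), linguistic features
    (part-of-speech frequencies, stop-word counts, TF-IDF keyword vectors),
    negation-aware lexicon sentiment scoring, group comparison with
    Benjamini-Hochberg false discovery rate control, and a multi-classifier
    evaluation harness with stratified splitting, SMOTE oversampling,
    cross-validation and permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    pROC,
    rpart,
    class,
    e1071,
    randomForest,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
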