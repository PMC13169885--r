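# voicemark

Speech and language biomarkers for differentiating bipolar disorder (BP)
from major depressive disorder (MDD) in euthymic patients.

Distinguishing BP from MDD matters clinically — a bipolar patient assessed
during a depressive phase is frequently misdiagnosed as unipolar — and
speech is a promising non-invasive marker even during symptom-free
periods: euthymic BP speakers tend to produce more words with shorter
pauses and flatter amplitude than euthymic MDD speakers. `voicemark`
implements the full analysis pipeline for short (~60 s) monologue
recordings and their transcripts:

* **Acoustic features** — pause detection on a short-window RMS envelope,
  gated at 35 dB below the recording's reference level with a 200 ms
  minimum and a 500 ms credited-duration cap; cumulative pause ratios
  (pause/duration, pause/word); and amplitude statistics, including the
  crest-factor rule `average peak = RMS × 1.414`.
* **Linguistic features** — 13 part-of-speech frequencies (pluggable
  tagger), stop-word counting/removal, and a TF-IDF keyword vector
  (`TFIDF_{i,j} = TF_{i,j} × IDF_i`, top 75 terms by corpus-summed mass).
* **Sentiment features** — negation-aware lexicon polarity
  (`Score(w) = Negation × Orientation(w)`, mean-aggregated into a score in
  [−1, 1]), five annotation-class frequencies, and eight
  negation-weighted emotion frequencies.
* **Statistics** — per-variable Welch t / chi-squared group comparisons
  with Benjamini–Hochberg FDR control across the pooled feature families.
* **Modeling** — a 118-column feature matrix (10 demographic + 13 POS +
  75 TF-IDF + 14 sentiment + 6 acoustic), stratified 4:1 split, SMOTE
  oversampling inside each CV fold, an eight-family classifier panel
  (decision tree, k-NN, elastic-net and plain logistic regression, SVM,
  naive Bayes, random forest, gradient-boosted trees), and permutation
  feature importance.

Because clinical recordings of this kind are not publicly distributable,
the package ships a **synthetic cohort generator** with known ground truth
(pause fractions, amplitudes, word counts, lexicon-class compositions,
demographic tables) calibrated to the published group directions. Every
extractor is validated against that ground truth and against independent
brute-force oracles.

## Worked example

```r
library(voicemark)

# default study shape: 41 BP + 150 MDD synthetic subjects, ~60 s audio each
fm <- simulate_feature_matrix(default_cohort_config(), seed = 1)
dim(fm)                      # 191 subjects x (118 features + id + label)

ct <- build_comparison_tables(fm)
ct[ct$family == "Acoustic", c("variable", "summary_a", "summary_b",
                              "p_adj", "significant")]
```

```
                variable        summary_a        summary_b     p_adj significant
1     pause_per_duration  0.1890 (0.0583)  0.3001 (0.1209)  4.66e-18        TRUE
2         pause_per_word  0.0563 (0.0218)  0.1278 (0.0619)  6.26e-28        TRUE
3         peak_amplitude  0.2611 (0.0233)  0.8043 (0.1178) 6.48e-135        TRUE
4     max_peak_amplitude  0.2611 (0.0233)  0.8043 (0.1178) 6.48e-135        TRUE
5     min_peak_amplitude -0.2611 (0.0233) -0.8043 (0.1178) 6.48e-135        TRUE
6 average_peak_amplitude  0.1215 (0.0109)  0.2995 (0.0332) 7.33e-137        TRUE
```

Summaries are `group mean (IQR)` for the BP and MDD groups; the generator
injects shorter pauses and lower, flatter amplitude for BP, and the
comparison layer recovers exactly those rows as significant after FDR
adjustment (sentiment and POS rows, whose generator distributions differ
only marginally, stay mostly non-significant).

```r
sp  <- split_cohort(fm, ratio = 0.2, seed = 1)   # stratified 4:1; 8 BP in test
rep <- train_and_evaluate(sp$train, sp$test, cv_folds = 10, seed = 1)
rep$metrics[rep$metrics$split == "test", ]
```

```
  classifier split   auc sensitivity specificity precision accuracy    f1
1         DT  test 1.000       1.000      1.0000     1.000    1.000 1.000
2        KNN  test 0.733       1.000      0.0667     0.222    0.263 0.364
3     GLMNET  test 1.000       1.000      1.0000     1.000    1.000 1.000
4         LR  test 0.977       1.000      0.9333     0.800    0.947 0.889
5        SVM  test 1.000       0.875      1.0000     1.000    0.974 0.933
6         NB  test 1.000       1.000      1.0000     1.000    1.000 1.000
7         RF  test 1.000       1.000      1.0000     1.000    1.000 1.000
8        XGB  test 1.000       1.000      1.0000     1.000    1.000 1.000
```

The synthetic group separation is deliberately strong, so most families
reach ceiling performance here — the suite's honesty checks are the
interesting part: label-shuffled cohorts score at chance (mean test AUC in
[0.45, 0.55] over 50 seeds) and an always-positive classifier reproduces
the degenerate pattern sensitivity 1 / specificity 0 / precision = test
prevalence.

Permutation importance is most informative when groups differ in a single
feature block (under the default profiles the signal is redundant across
many columns, so single-column permutations barely move a random forest).
With profiles that differ only in pause behaviour (point-mass pause
fractions 0.15 vs 0.35, identical amplitude/word distributions), the
acoustic ratios dominate the ranking:

```r
# cfg: BP/MDD profiles differing only in pause_fraction; RF fitted as above
imp <- permutation_importance(rep$fitted$RF, "RF", sp$test, seed = 7)
head(imp, 2)
#              feature importance rank
# 1 pause_per_duration      0.071    1
# 2     pause_per_word      0.033    2
```

A full run (`run_pipeline("out/", seed = 1)`) writes `features.csv`,
`comparisons.csv`, `model_report.csv`, `importance.csv` and the resolved
`run_config.yaml`. A thin command-line wrapper with `simulate`,
`extract-audio`, `compare`, `train` and `all` subcommands lives at
`inst/cli/voicemark.R`.

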