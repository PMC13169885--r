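# Classification harness

# build a light feature matrix directly (no audio synthesis) for harness tests
make_fm <- function(n_bp = 20, n_mdd = 60, p_noise = 8, sep = 0, seed = 81) {
  set.seed(seed)
  n <- n_bp + n_mdd
  label <- c(rep("BP", n_bp), rep("MDD", n_mdd))
  x <- matrix(rnorm(n * p_noise), n)
  colnames(x) <- sprintf("f%02d", seq_len(p_noise))
  if (sep > 0) {
    x[, 1] <- x[, 1] + ifelse(label == "BP", sep, 0)
    x[, 2] <- x[, 2] - ifelse(label == "BP", sep, 0)
  }
  out <- tibble::as_tibble(cbind(
    data.frame(subject_id = sprintf("S%03d", seq_len(n)), label = label,
               stringsAsFactors = FALSE),
    as.data.frame(x)))
  out
}

test_that("assembly produces the canonical 118-column layout", {
  cfg <- list(BP = fast_profile("BP", 6, dur = 6),
              MDD = fast_profile("MDD", 8, dur = 6))
  fm <- simulate_feature_matrix(cfg, seed = 82)
  feat <- setdiff(names(fm), c("subject_id", "label"))
  expect_length(feat, 118)
  fam <- attr(fm, "family")
  expect_equal(as.vector(table(fam)[c("Demographic", "Sentiment", "Acoustic")]),
               c(10L, 14L, 6L))
  expect_equal(sum(fam == "Linguistic"), 13 + 75)
  expect_equal(sum(startsWith(names(fam), "pos_")), 13)
  expect_equal(sum(startsWith(names(fam), "tfidf_")), 75)
  expect_false(any(is.na(fm$label)))
})

test_that("extended assembly appends the five extra textual variables", {
  cfg <- list(BP = fast_profile("BP", 5, dur = 6),
              MDD = fast_profile("MDD", 5, dur = 6))
  fm <- simulate_feature_matrix(cfg, seed = 83, extended = TRUE)
  feat <- setdiff(names(fm), c("subject_id", "label"))
  expect_length(feat, 123)
  expect_true(all(c("total_word_count", "speaking_rate", "stop_word_count",
                    "tfidf_top_word_sum", "tfidf_top_word_sum_per_word")
                  %in% feat))
})

test_that("subjects missing a block or transcript abort assembly by name", {
  lex <- build_synthetic_lexicon()
  rec <- list(list(id = "S1", label = "BP", tokens = c("a", "b"),
                   demographics = sample_demographics(fast_profile("BP", 1)),
                   audio = list(total_duration_s = 10, pause_total_s = 1,
                                pause_per_duration = 0.1,
                                pause_per_word = 0.5, peak_amplitude = 0.3,
                                max_peak_amplitude = 0.3,
                                min_peak_amplitude = -0.3,
                                average_peak_amplitude = 0.1)))
  broken <- rec
  broken[[1]]$audio <- NULL
  expect_error(assemble_features(broken, lex), "S1 missing block")
  empty <- rec
  empty[[1]]$tokens <- character(0)
  expect_error(assemble_features(empty, lex), "empty transcript")
})

test_that("the stratified 4:1 split reproduces the expected class balance", {
  fm <- make_fm(41, 150)
  sp <- split_cohort(fm, ratio = 0.2, seed = 84)
  expect_equal(sum(sp$test$label == "BP"), 8)
  expect_equal(sum(sp$test$label == "MDD"), 30)
  expect_equal(nrow(sp$train) + nrow(sp$test), 191)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  sp2 <- split_cohort(fm, ratio = 0.2, seed = 84)
  expect_identical(sp$test$subject_id, sp2$test$subject_id)
  expect_error(split_cohort(make_fm(1, 10), 0.2, 1), "split error")
})

test_that("SMOTE balances classes with convex synthetic rows", {
  fm <- make_fm(33, 120)
  x <- as.matrix(fm[, -(1:2)])
  bal <- smote(x, fm$label, seed = 85)
  expect_equal(as.vector(table(bal$y)), c(120L, 120L))
  syn <- bal$x[-seq_len(nrow(x)), , drop = FALSE]
  min_box <- apply(x[fm$label == "BP", ], 2, range)
  for (j in seq_len(ncol(syn))) {
    expect_gte(min(syn[, j]), min_box[1, j] - 1e-9)
    expect_lte(max(syn[, j]), min_box[2, j] + 1e-9)
  }
  # already balanced input is untouched
  fmb <- make_fm(10, 10)
  balb <- smote(as.matrix(fmb[, -(1:2)]), fmb$label, seed = 85)
  expect_equal(nrow(balb$x), 20)
  # k is reduced with a warning for tiny minorities
  fms <- make_fm(4, 30)
  expect_warning(smote(as.matrix(fms[, -(1:2)]), fms$label, seed = 85),
                 "k reduced")
})

test_that("metrics agree with the confusion matrix identities", {
  y <- c(rep("BP", 4), rep("MDD", 6))
  p <- c(0.9, 0.8, 0.4, 0.3, 0.6, 0.2, 0.1, 0.3, 0.2, 0.55)
  m <- classification_metrics(y, p)
  tp <- 2; fp <- 2; fn <- 2; tn <- 4
  expect_equal(unname(m["sensitivity"]), tp / (tp + fn))
  expect_equal(unname(m["specificity"]), tn / (tn + fp))
  expect_equal(unname(m["precision"]), tp / (tp + fp))
  expect_equal(unname(m["accuracy"]), (tp + tn) / 10)
  f1 <- 2 * m["precision"] * m["sensitivity"] /
    (m["precision"] + m["sensitivity"])
  expect_equal(unname(m["f1"]), unname(f1), tolerance = 1e-9)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("an always-positive classifier shows the degenerate pattern", {
  fm <- make_fm(20, 60, sep = 1)
  sp <- split_cohort(fm, 0.2, seed = 86)
  rep_ <- train_and_evaluate(sp$train, sp$test, cv_folds = 3, seed = 86,
                             classifiers = "CONSTANT_POSITIVE")
  te <- rep_$metrics[rep_$metrics$split == "test", ]
  expect_equal(te$sensitivity, 1)
  expect_equal(te$specificity, 0)
  prevalence <- mean(sp$test$label == "BP")
  expect_equal(te$precision, prevalence)
})

test_that("the panel separates an injected class difference", {
  fm <- make_fm(25, 60, sep = 2.5)
  sp <- split_cohort(fm, 0.2, seed = 87)
  rep_ <- train_and_evaluate(sp$train, sp$test, cv_folds = 5, seed = 87,
                             classifiers = c("DT", "KNN", "GLMNET", "LR",
                                             "SVM", "NB", "RF", "XGB"))
  expect_equal(nrow(rep_$metrics), 16)
  te <- rep_$metrics[rep_$metrics$split == "test", ]
  expect_gte(max(te$auc), 0.75)
  expect_true(all(te$auc >= 0 & te$auc <= 1))
  tr <- rep_$metrics[rep_$metrics$split == "train", ]
  expect_true(all(is.finite(tr$auc)))
  expect_named(rep_$lockfile$settings, c("DT", "KNN", "GLMNET", "LR",
                                         "SVM", "NB", "RF", "XGB"))
})

test_that("training never touches the held-out rows", {
  fm <- make_fm(15, 40, sep = 1)
  sp <- split_cohort(fm, 0.2, seed = 88)
  before <- as.matrix(sp$test[, -(1:2)])
  rep_ <- train_and_evaluate(sp$train, sp$test, cv_folds = 3, seed = 88,
                             classifiers = c("LR", "NB"))
  expect_identical(as.matrix(sp$test[, -(1:2)]), before)
  expect_length(rep_$test_scores$LR, nrow(sp$test))
})

test_that("permutation importance ranks the informative feature first", {
  fm <- make_fm(25, 60, sep = 0, p_noise = 6, seed = 89)
  # inject signal in exactly one (audio-like) column
  fm$f01 <- fm$f01 + ifelse(fm$label == "BP", 3, 0)
  sp <- split_cohort(fm, 0.3, seed = 89)
  rep_ <- train_and_evaluate(sp$train, sp$test, cv_folds = 3, seed = 89,
                             classifiers = "RF")
  imp <- permutation_importance(rep_$fitted$RF, "RF", sp$test, seed = 89)
  expect_equal(imp$feature[1], "f01")
  imp2 <- permutation_importance(rep_$fitted$RF, "RF", sp$test, seed = 89)
  expect_identical(imp, imp2)
  # a constant feature cannot matter
  fmc <- fm
  fmc$f06 <- 1
  spc <- split_cohort(fmc, 0.3, seed = 90)
  repc <- train_and_evaluate(spc$train, spc$test, cv_folds = 3, seed = 90,
                             classifiers = "RF")
  impc <- permutation_importance(repc$fitted$RF, "RF", spc$test, seed = 90)
  expect_equal(impc$importance[impc$feature == "f06"], 0, tolerance = 1e-9)
})

test_that("label-shuffled data scores at chance on average", {
  fm <- make_fm(20, 50, sep = 2)
  set.seed(91)
  aucs <- vapply(seq_len(12), function(i) {
    fs <- fm
    fs$label <- sample(fs$label)
    sp <- split_cohort(fs, 0.25, seed = i)
    r <- train_and_evaluate(sp$train, sp$test, cv_folds = 3, seed = i,
                            classifiers = "NB")
    r$metrics$auc[r$metrics$split == "test"]
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})
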