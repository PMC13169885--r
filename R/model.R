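# Classification harness -----------------------------------------------------
#
# The positive class is BP throughout: sensitivity is the BP true-positive
# rate and precision the positive predictive value for BP.

.positive_class <- "BP"

#' Stratified train/test split
#'
#' Splits subjects 4:1 (by default) within each label stratum, reproducibly
#' for a fixed seed. With the default 41 + 150 cohort the test partition
#' contains 8 BP subjects.
#'
#' @param fm A `vm_features` feature matrix (or any data frame with `label`).
#' @param ratio Test fraction in (0, 1), default 0.2.
#' @param seed Integer seed.
#' @return List with `train` and `test` (same class as `fm`).
#' @export
split_cohort <- function(fm, ratio = 0.2, seed = 1) {
  stopifnot(ratio > 0, ratio < 1)
  tab <- table(fm$label)
  if (length(tab) < 2 || any(tab < 2))
    stop("split error: both classes need at least 2 members")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  test_idx <- unlist(lapply(names(tab), function(lv) {
    idx <- which(fm$label == lv)
    n_test <- max(1L, round(length(idx) * ratio))
    sample(idx, n_test)
  }))
  list(train = fm[-test_idx, , drop = FALSE],
       test = fm[sort(test_idx), , drop = FALSE])
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic minority rows are convex combinations of a minority row and one
#' of its k nearest minority neighbours (Euclidean distance over all
#' feature columns). Applied to training data only; class counts are equal
#' afterwards. If the minority class has at most `k_neighbors` members, k is
#' reduced with a warning.
#'
#' @param x Numeric feature matrix (rows = subjects).
#' @param y Label vector.
#' @param k_neighbors Number of nearest neighbours (default 5).
#' @param seed Optional seed; uses the current RNG state when `NULL`.
#' @return List with oversampled `x` and `y`.
#' @export
smote <- function(x, y, k_neighbors = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  tab <- table(y)
  if (length(tab) != 2) stop("smote: exactly two classes required")
  minority <- names(tab)[which.min(tab)]
  n_needed <- max(tab) - min(tab)
  if (n_needed == 0) return(list(x = x, y = y))
  min_x <- x[y == minority, , drop = FALSE]
  n_min <- nrow(min_x)
  k <- k_neighbors
  if (n_min <= k) {
    k <- n_min - 1L
    warning("smote: minority count ", n_min, " <= k_neighbors; k reduced to ", k)
  }
  if (k < 1) stop("smote: minority class too small to interpolate")
  d <- as.matrix(stats::dist(min_x))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  base_i <- sample.int(n_min, n_needed, replace = TRUE)
  nn_j <- vapply(base_i, function(i) nn[i, sample.int(k, 1)], integer(1))
  gap <- stats::runif(n_needed)
  syn <- min_x[base_i, , drop = FALSE] +
    gap * (min_x[nn_j, , drop = FALSE] - min_x[base_i, , drop = FALSE])
  list(x = rbind(x, syn), y = c(y, rep(minority, n_needed)))
}

# --- classifier registry -----------------------------------------------------

# each entry: fit(x, y) -> model object; prob(model, x) -> P(BP)
# y is a factor with levels c("MDD", "BP") (positive class second)
classifier_registry <- function() {
  scale_fit <- function(x) {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    sd[sd == 0] <- 1
    list(mu = mu, sd = sd)
  }
  scale_apply <- function(x, s) sweep(sweep(x, 2, s$mu), 2, s$sd, "/")
  list(
    DT = list(
      fit = function(x, y) rpart::rpart(y ~ ., data = data.frame(x, y = y),
                                        method = "class"),
      prob = function(m, x) stats::predict(m, data.frame(x), type = "prob")[, .positive_class]),
    KNN = list(
      fit = function(x, y) {
        s <- scale_fit(x)
        list(x = scale_apply(x, s), y = y, s = s, k = 5L)
      },
      prob = function(m, x) {
        pr <- class::knn(m$x, scale_apply(x, m$s), m$y, k = m$k, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == .positive_class, p, 1 - p)
      }),
    GLMNET = list(
      fit = function(x, y) glmnet::cv.glmnet(as.matrix(x), y,
                                             family = "binomial", nfolds = 5),
      prob = function(m, x) as.numeric(stats::predict(m, as.matrix(x),
                                                      s = "lambda.min",
                                                      type = "response"))),
    LR = list(
      fit = function(x, y) suppressWarnings(
        stats::glm(y ~ ., data = data.frame(x, y = y), family = stats::binomial())),
      prob = function(m, x) suppressWarnings(
        as.numeric(stats::predict(m, data.frame(x), type = "response")))),
    SVM = list(
      fit = function(x, y) e1071::svm(x, y, probability = TRUE),
      prob = function(m, x) {
        pr <- stats::predict(m, x, probability = TRUE)
        attr(pr, "probabilities")[, .positive_class]
      }),
    NB = list(
      fit = function(x, y) {
        # drop columns that are constant within a class: Gaussian NB has no
        # density there
        keep <- vapply(seq_len(ncol(x)), function(j) {
          all(tapply(x[, j], y, stats::sd) > 0)
        }, logical(1))
        if (!any(keep)) keep[1] <- TRUE
        list(m = e1071::naiveBayes(x[, keep, drop = FALSE], y), keep = keep)
      },
      prob = function(m, x) stats::predict(m$m, x[, m$keep, drop = FALSE],
                                           type = "raw")[, .positive_class]),
    RF = list(
      fit = function(x, y) randomForest::randomForest(x, y),
      prob = function(m, x) stats::predict(m, x, type = "prob")[, .positive_class]),
    XGB = list(
      fit = function(x, y) xgboost::xgboost(as.matrix(x), y, nrounds = 100,
                                            nthreads = 1, verbosity = 0),
      prob = function(m, x) {
        p <- stats::predict(m, as.matrix(x), type = "response")
        if (is.matrix(p)) p[, .positive_class] else p
      }),
    CONSTANT_POSITIVE = list(
      fit = function(x, y) list(),
      prob = function(m, x) rep(1, nrow(x)))
  )
}

#' Names of the default classifier families
#' @return Character vector of the eight default registry entries.
#' @export
default_classifiers <- function() {
  c("DT", "KNN", "GLMNET", "LR", "SVM", "NB", "RF", "XGB")
}

#' Classification metrics from scores and labels
#'
#' AUC (BP as positive class), plus threshold-0.5 confusion-matrix metrics:
#' sensitivity, specificity, precision, accuracy, F1. Precision is 0 when no
#' positive predictions exist; AUC is `NA` for degenerate single-class
#' truth.
#'
#' @param y True labels.
#' @param p Predicted `P(BP)`.
#' @return Named numeric vector.
#' @export
classification_metrics <- function(y, p) {
  pos <- y == .positive_class
  pred_pos <- p >= 0.5
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos); fp <- sum(!pos & pred_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  acc <- (tp + tn) / length(y)
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  auc <- if (length(unique(y)) == 2 && length(unique(p)) > 1) {
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = p,
                                   levels = c("MDD", .positive_class),
                                   direction = "<", quiet = TRUE)))
  } else if (length(unique(y)) == 2) 0.5 else NA_real_
  c(auc = auc, sensitivity = sens, specificity = spec, precision = prec,
    accuracy = acc, f1 = f1)
}

#' Train and evaluate the classifier panel
#'
#' Fits each classifier family on the SMOTE-balanced training partition and
#' evaluates on the untouched holdout. Training metrics are the arithmetic
#' mean over stratified cross-validation folds of the training partition;
#' SMOTE is applied inside each fold by default (leakage-safe), or once to
#' the whole training set with `smote_mode = "global"`. Numeric settings of
#' every family are pinned in the returned lockfile entry.
#'
#' @param train,test Feature matrices from [split_cohort()].
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment, SMOTE and the
#'   stochastic learners.
#' @param classifiers Character vector of registry names (default the eight
#'   default families).
#' @param smote_mode `"per_fold"` (default) or `"global"`.
#' @param use_smote Apply SMOTE at all (default `TRUE`).
#' @return A `vm_model_report`: list with `metrics` (tibble: classifier,
#'   split, auc, sensitivity, specificity, precision, accuracy, f1),
#'   `fitted` (final fitted models), `lockfile` (resolved settings), and the
#'   test partition's labels/scores per classifier.
#' @export
train_and_evaluate <- function(train, test, cv_folds = 10, seed = 1,
                               classifiers = default_classifiers(),
                               smote_mode = c("per_fold", "global"),
                               use_smote = TRUE) {
  smote_mode <- match.arg(smote_mode)
  registry <- classifier_registry()
  unknown <- setdiff(classifiers, names(registry))
  if (length(unknown))
    stop("unknown classifier(s): ", paste(unknown, collapse = ", "))
  feat_cols <- setdiff(names(train), c("subject_id", "label"))
  x_tr <- as.matrix(as.data.frame(train[, feat_cols]))
  y_tr <- factor(train$label, levels = c("MDD", .positive_class))
  x_te <- as.matrix(as.data.frame(test[, feat_cols]))
  y_te <- factor(test$label, levels = c("MDD", .positive_class))
  test_hash_before <- digest_rows(x_te)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # stratified fold assignment
  folds <- integer(nrow(x_tr))
  for (lv in levels(y_tr)) {
    idx <- which(y_tr == lv)
    folds[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }

  global_bal <- if (use_smote && smote_mode == "global")
    smote(x_tr, as.character(y_tr)) else NULL

  rows <- list()
  fitted <- list()
  scores <- list()
  for (nm in classifiers) {
    cl <- registry[[nm]]
    fold_metrics <- matrix(NA_real_, nrow = cv_folds, ncol = 6)
    for (f in seq_len(cv_folds)) {
      tr_i <- folds != f
      if (length(unique(y_tr[!tr_i])) < 2 && sum(!tr_i) > 0) {
        # degenerate single-class fold cannot score AUC; skip it in the mean
      }
      if (use_smote && smote_mode == "per_fold") {
        bal <- smote(x_tr[tr_i, , drop = FALSE], as.character(y_tr[tr_i]))
        fx <- bal$x; fy <- factor(bal$y, levels = levels(y_tr))
      } else if (!is.null(global_bal)) {
        keep <- c(which(tr_i), nrow(x_tr) + seq_len(nrow(global_bal$x) - nrow(x_tr)))
        fx <- global_bal$x[keep, , drop = FALSE]
        fy <- factor(global_bal$y[keep], levels = levels(y_tr))
      } else {
        fx <- x_tr[tr_i, , drop = FALSE]; fy <- y_tr[tr_i]
      }
      m <- cl$fit(fx, fy)
      p <- cl$prob(m, x_tr[!tr_i, , drop = FALSE])
      fold_metrics[f, ] <- classification_metrics(as.character(y_tr[!tr_i]), p)
    }
    train_m <- colMeans(fold_metrics, na.rm = TRUE)
    names(train_m) <- c("auc", "sensitivity", "specificity", "precision",
                        "accuracy", "f1")
    if (use_smote) {
      bal <- smote(x_tr, as.character(y_tr))
      final <- cl$fit(bal$x, factor(bal$y, levels = levels(y_tr)))
    } else {
      final <- cl$fit(x_tr, y_tr)
    }
    p_te <- cl$prob(final, x_te)
    test_m <- classification_metrics(as.character(y_te), p_te)
    fitted[[nm]] <- final
    scores[[nm]] <- p_te
    as_row <- function(split, m) {
      m <- unname(m)
      tibble::tibble(classifier = nm, split = split, auc = m[1],
                     sensitivity = m[2], specificity = m[3], precision = m[4],
                     accuracy = m[5], f1 = m[6])
    }
    rows[[length(rows) + 1]] <- as_row("train", train_m)
    rows[[length(rows) + 1]] <- as_row("test", test_m)
  }
  if (!identical(digest_rows(x_te), test_hash_before))
    stop("leakage guard: test rows were modified during training")
  lock <- list(cv_folds = cv_folds, seed = seed, smote = use_smote,
               smote_mode = smote_mode, smote_k = 5,
               positive_class = .positive_class,
               settings = list(DT = "rpart defaults",
                               KNN = "k = 5, z-scored features",
                               GLMNET = "cv.glmnet binomial, lambda.min, 5 inner folds",
                               LR = "glm binomial",
                               SVM = "e1071 RBF defaults, probability = TRUE",
                               NB = "Gaussian naive Bayes",
                               RF = "randomForest defaults (500 trees)",
                               XGB = "xgboost defaults, nrounds = 100"))
  structure(list(metrics = do.call(rbind, rows), fitted = fitted,
                 test_scores = scores, test_labels = as.character(y_te),
                 feature_cols = feat_cols, lockfile = lock),
            class = "vm_model_report")
}

# cheap deterministic content hash for the leakage guard
digest_rows <- function(x) {
  paste(dim(x)[1], dim(x)[2], format(sum(x * seq_along(x)), digits = 22),
        format(sum(abs(x)), digits = 22))
}

#' Permutation feature importance
#'
#' Mean AUC drop over `n_repeats` permutations of each feature column,
#' evaluated with a fitted registry classifier on a held-out data set.
#' Features are ranked by descending importance, ties broken by name.
#'
#' @param model A fitted model from a [train_and_evaluate()] report
#'   (`report$fitted[[name]]`).
#' @param classifier Registry name of the model (for the predict method).
#' @param data Feature matrix (e.g. the test partition).
#' @param n_repeats Permutations per feature (default 10).
#' @param seed Integer seed.
#' @return Tibble with `feature`, `importance` (mean AUC drop), `rank`.
#' @export
permutation_importance <- function(model, classifier, data, n_repeats = 10,
                                   seed = 1) {
  registry <- classifier_registry()
  cl <- registry[[classifier]]
  feat_cols <- setdiff(names(data), c("subject_id", "label"))
  x <- as.matrix(as.data.frame(data[, feat_cols]))
  y <- as.character(data$label)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  base_auc <- classification_metrics(y, cl$prob(model, x))["auc"]
  imp <- vapply(feat_cols, function(v) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, v] <- sample(xp[, v])
      base_auc - classification_metrics(y, cl$prob(model, xp))["auc"]
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  ord <- order(-imp, feat_cols)
  tibble::tibble(feature = feat_cols[ord], importance = unname(imp[ord]),
                 rank = seq_along(ord))
}
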