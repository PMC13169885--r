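# Pipeline orchestration -----------------------------------------------------

#' Run configuration
#'
#' Bundles every tunable of the pipeline with its default: the pause
#' detector gate (35 dB, 200-500 ms), the TF-IDF keyword count (75, sweep
#' range 50-500), the test split ratio (0.2), cross-validation folds (10),
#' the significance level (0.05) and the FDR pooling mode. Every pipeline
#' run writes its resolved configuration next to its outputs.
#'
#' @param threshold_db,min_ms,max_ms Pause detector settings.
#' @param noise_profile_s Noise-reduction profile seconds (0 = off).
#' @param k,k_bounds TF-IDF keyword count and allowed range.
#' @param ratio Test fraction.
#' @param cv_folds Cross-validation folds.
#' @param alpha Significance level for the comparison tables.
#' @param pooling FDR family pooling (`"pooled"` or `"per_family"`).
#' @param extended Include the five extra textual variables.
#' @param classifiers Classifier families to train.
#' @return Named list of class `vm_config`.
#' @export
run_config <- function(threshold_db = 35, min_ms = 200, max_ms = 500,
                       noise_profile_s = 0, k = 75, k_bounds = c(50, 500),
                       ratio = 0.2, cv_folds = 10, alpha = 0.05,
                       pooling = "pooled", extended = FALSE,
                       classifiers = default_classifiers()) {
  structure(list(threshold_db = threshold_db, min_ms = min_ms,
                 max_ms = max_ms, noise_profile_s = noise_profile_s,
                 k = k, k_bounds = k_bounds, ratio = ratio,
                 cv_folds = cv_folds, alpha = alpha, pooling = pooling,
                 extended = extended, classifiers = classifiers),
            class = "vm_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> extract -> compare -> train and writes four
#' artifacts into `out_dir`: `features.csv`, `comparisons.csv`,
#' `model_report.csv`, `importance.csv`, plus `run_config.yaml` recording
#' the resolved configuration, seed and hyperparameter lockfile. All
#' randomness flows from the single root seed.
#'
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param config A [run_config()].
#' @param cohort_config Named list of [group_profile()]s.
#' @param seed Integer root seed.
#' @param train_models Fit the classifier panel (default `TRUE`).
#' @return List with `features`, `comparisons`, `split`, `report`,
#'   `importance` (invisibly when `out_dir` is given).
#' @export
run_pipeline <- function(out_dir = NULL, config = run_config(),
                         cohort_config = default_cohort_config(), seed = 1,
                         train_models = TRUE) {
  seeds <- split_seed(seed, 3)
  fm <- simulate_feature_matrix(cohort_config, seed = seeds[1], k = config$k,
                                extended = config$extended,
                                threshold_db = config$threshold_db,
                                min_ms = config$min_ms,
                                max_ms = config$max_ms,
                                noise_profile_s = config$noise_profile_s)
  comparisons <- build_comparison_tables(fm, alpha = config$alpha,
                                         pooling = config$pooling)
  split <- split_cohort(fm, ratio = config$ratio, seed = seeds[2])
  report <- NULL
  importance <- NULL
  if (train_models) {
    report <- train_and_evaluate(split$train, split$test,
                                 cv_folds = config$cv_folds,
                                 seed = seeds[3],
                                 classifiers = config$classifiers)
    best <- report$metrics[report$metrics$split == "test", ]
    best <- best$classifier[which.max(best$auc)]
    importance <- permutation_importance(report$fitted[[best]], best,
                                         split$test, seed = seeds[3])
  }
  out <- list(features = fm, comparisons = comparisons, split = split,
              report = report, importance = importance, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(fm), file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(comparisons),
                     file.path(out_dir, "comparisons.csv"), row.names = FALSE)
    if (!is.null(report))
      utils::write.csv(as.data.frame(report$metrics),
                       file.path(out_dir, "model_report.csv"),
                       row.names = FALSE)
    if (!is.null(importance))
      utils::write.csv(as.data.frame(importance),
                       file.path(out_dir, "importance.csv"),
                       row.names = FALSE)
    yaml::write_yaml(c(unclass(config), list(seed = seed),
                       if (!is.null(report)) list(lockfile = report$lockfile)),
                     file.path(out_dir, "run_config.yaml"))
    return(invisible(out))
  }
  out
}

#' Render a comparison table as markdown
#'
#' @param comparisons Output of [build_comparison_tables()].
#' @return Character vector of markdown lines.
#' @export
render_comparison_markdown <- function(comparisons) {
  gr <- attr(comparisons, "groups") %||% c("A", "B")
  hdr <- sprintf("| Variable | Family | %s | %s | p | adj. p | sig |",
                 gr[1], gr[2])
  sep <- "|---|---|---|---|---|---|---|"
  body <- sprintf("| %s | %s | %s | %s | %.3g | %.3g | %s |",
                  comparisons$variable, comparisons$family,
                  comparisons$summary_a, comparisons$summary_b,
                  comparisons$p, comparisons$p_adj,
                  ifelse(comparisons$significant, "*", ""))
  c(hdr, sep, body)
}
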