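# Group comparison with FDR control ------------------------------------------

#' Compare a continuous variable between two groups
#'
#' Two-sided Welch (unequal-variance) t-test, chosen for the unequal group
#' sizes. Summaries report mean and interquartile range per group. When both
#' groups are constant the p-value is 1 for equal means and 0 otherwise.
#'
#' @param x,y Numeric vectors for the two groups (each length >= 2).
#' @return List: `p`, `mean_x`, `mean_y`, `iqr_x`, `iqr_y`, `median_x`,
#'   `median_y`.
#' @export
compare_continuous <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("test error: each group needs n >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("test error: non-finite values")
  p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  } else {
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }
  list(p = p, mean_x = mean(x), mean_y = mean(y),
       iqr_x = stats::IQR(x), iqr_y = stats::IQR(y),
       median_x = stats::median(x), median_y = stats::median(y))
}

#' Compare a categorical variable between groups
#'
#' Pearson chi-squared test on an r x c contingency table, without
#' continuity correction.
#'
#' @param tab Matrix or table of non-negative integer counts.
#' @return List with `p` and `statistic`.
#' @export
compare_categorical <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("test error: counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("test error: degenerate margin in contingency table")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(p = unname(res$p.value), statistic = unname(res$statistic))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, monotone-enforced and aligned with the input
#' order.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("input error: p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Build per-family group comparison tables
#'
#' For every feature column, runs a Welch t-test (continuous columns) or a
#' Pearson chi-squared test on the label-by-level contingency table
#' (categorical columns), then adjusts p-values with Benjamini-Hochberg.
#' By default the FDR family pools all variables across the four feature
#' families; `pooling = "per_family"` adjusts within each family instead.
#'
#' @param fm A feature matrix from [assemble_features()] (or any tibble with
#'   `label`, feature columns, and a `family` attribute), or a plain data
#'   frame with a `label` column, in which case all non-label columns form
#'   one family.
#' @param alpha Significance level on the adjusted scale (default 0.05).
#' @param pooling `"pooled"` (default) or `"per_family"`.
#' @return A tibble with columns `variable`, `family`, `summary_a`
#'   `summary_b` (formatted `mean (IQR)` or counts), `mean_a`, `mean_b`,
#'   `median_a`, `median_b`, `p`, `p_adj`, `significant`.
#' @export
build_comparison_tables <- function(fm, alpha = 0.05,
                                    pooling = c("pooled", "per_family")) {
  pooling <- match.arg(pooling)
  stopifnot("label" %in% names(fm))
  labels <- fm$label
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("test error: exactly two groups required")
  fam_map <- attr(fm, "family")
  cat_set <- attr(fm, "categorical")
  vars <- setdiff(names(fm), c("subject_id", "label"))
  rows <- lapply(vars, function(v) {
    col <- fm[[v]]
    fam <- if (!is.null(fam_map) && v %in% names(fam_map)) fam_map[[v]] else "feature"
    is_cat <- v %in% cat_set || !is.numeric(col) || length(unique(col)) <= 2
    if (!is_cat) {
      ok <- is.finite(col)
      if (sum(ok) < length(col)) col <- col[ok]
      r <- compare_continuous(col[labels[ok] == lv[1]], col[labels[ok] == lv[2]])
      tibble::tibble(variable = v, family = fam,
                     summary_a = sprintf("%.4f (%.4f)", r$mean_x, r$iqr_x),
                     summary_b = sprintf("%.4f (%.4f)", r$mean_y, r$iqr_y),
                     mean_a = r$mean_x, mean_b = r$mean_y,
                     median_a = r$median_x, median_b = r$median_y,
                     p = r$p)
    } else {
      tab <- table(labels, col)
      r <- tryCatch(compare_categorical(tab), error = function(e) list(p = NA_real_))
      cnt <- function(g) paste(sprintf("%s:%d", colnames(tab), tab[g, ]), collapse = " ")
      tibble::tibble(variable = v, family = fam,
                     summary_a = cnt(lv[1]), summary_b = cnt(lv[2]),
                     mean_a = NA_real_, mean_b = NA_real_,
                     median_a = NA_real_, median_b = NA_real_,
                     p = r$p)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  if (pooling == "pooled") {
    out$p_adj[ok] <- bh_fdr(out$p[ok])
  } else {
    for (f in unique(out$family)) {
      idx <- ok & out$family == f
      out$p_adj[idx] <- bh_fdr(out$p[idx])
    }
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  attr(out, "groups") <- lv
  out
}
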