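#' Two-sample Student's t-test (pooled variance)
#'
#' Two-sided equal-variance t-test comparing a feature's values between
#' poor-outcome (label 1) and good-outcome (label 0) patients, with the
#' p-value from the t distribution on n1 + n0 - 2 degrees of freedom. A
#' constant feature (zero pooled variance) is assigned t = 0, p = 1 with a
#' warning rather than being dropped, so feature universes stay aligned
#' across cohorts.
#'
#' @param values Numeric vector of per-patient feature values.
#' @param labels Binary 0/1 outcome vector, same length.
#' @return A list with `t_stat` and `p_value`.
#' @export
student_t_test <- function(values, labels) {
  if (length(values) != length(labels)) stop("values and labels differ in length")
  res <- row_t_test(matrix(values, nrow = 1), labels)
  list(t_stat = res$t_stat[1], p_value = res$p_value[1])
}

#' Row-wise pooled-variance t-tests
#'
#' Vectorized form of [student_t_test()] over the rows of a feature matrix.
#'
#' @param values Numeric matrix, features in rows, patients in columns.
#' @param labels Binary 0/1 outcome vector, one per column.
#' @return A data.frame with columns `t_stat` and `p_value`, one row per
#'   feature.
#' @export
row_t_test <- function(values, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (ncol(values) != length(labels)) stop("one label per column required")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < 2 || n0 < 2)
    stop("both outcome groups need >= 2 patients (have ", n1, " poor, ", n0, " good)")
  x1 <- values[, labels == 1L, drop = FALSE]
  x0 <- values[, labels == 0L, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  ss1 <- rowSums((x1 - m1)^2)
  ss0 <- rowSums((x0 - m0)^2)
  df <- n1 + n0 - 2L
  sp2 <- (ss1 + ss0) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t_stat <- ifelse(se > 0, (m1 - m0) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), df), 1)
  if (any(se == 0))
    warning(sum(se == 0), " constant feature(s) assigned p = 1")
  data.frame(t_stat = t_stat, p_value = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment: p-values sorted ascending are multiplied by
#' m/i, monotonicity is enforced from the largest down, results capped at 1
#' and returned in the original order.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Significance table for a feature matrix
#'
#' Runs a pooled-variance t-test per feature, BH-adjusts the p-values, and
#' ranks features by ascending raw p-value (ties broken by ascending feature
#' id). Ranking by raw p-values drives top-feature selection; adjusted
#' values gate only significance counts.
#'
#' @param fm A `FeatureMatrix`.
#' @param outcome Binary 0/1 outcome vector or a labelled
#'   `ExpressionDataset` from which to take it; must align with the feature
#'   matrix's patient columns.
#' @return A `SignificanceTable` data.frame: `feature_id`, `t_stat`,
#'   `p_value`, `p_adjusted`, `rank`.
#' @export
feature_significance <- function(fm, outcome) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  if (inherits(outcome, "ExpressionDataset")) {
    if (is.null(outcome$outcome)) stop("dataset has no outcome labels")
    outcome <- outcome$outcome[colnames(fm$values)]
  }
  tt <- row_t_test(fm$values, outcome)
  tab <- data.frame(feature_id = fm$feature_ids,
                    t_stat = tt$t_stat,
                    p_value = tt$p_value,
                    p_adjusted = bh_adjust(tt$p_value),
                    stringsAsFactors = FALSE)
  ord <- order(tab$p_value, tab$feature_id)
  tab$rank <- integer(nrow(tab))
  tab$rank[ord] <- seq_len(nrow(tab))
  attr(tab, "feature_type") <- fm$feature_type
  class(tab) <- c("SignificanceTable", "data.frame")
  tab
}

#' Count features passing an FDR threshold
#'
#' @param table A `SignificanceTable`.
#' @param fdr_threshold FDR-corrected p-value threshold (default 0.1).
#' @return Number of features with adjusted p-value <= threshold.
#' @export
count_significant <- function(table, fdr_threshold = 0.1) {
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("fdr_threshold must lie in (0, 1)")
  if (nrow(table) == 0) return(0L)
  sum(table$p_adjusted <= fdr_threshold)
}

#' Top-ranked feature ids
#'
#' Features sorted by ascending raw p-value, ties broken by ascending
#' feature id; the first `top_n` are returned.
#'
#' @param table A `SignificanceTable`.
#' @param top_n Number of features to return (<= number of features).
#' @return Character vector of feature ids, length `top_n`.
#' @export
rank_features <- function(table, top_n) {
  if (top_n > nrow(table))
    stop("top_n (", top_n, ") exceeds the number of features (", nrow(table), ")")
  ord <- order(table$p_value, table$feature_id)
  table$feature_id[ord][seq_len(top_n)]
}

#' Write a significance table to TSV
#'
#' @param table A `SignificanceTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_significance <- function(table, path) {
  data.table::fwrite(as.data.frame(table)[, c("feature_id", "t_stat", "p_value",
                                              "p_adjusted", "rank")],
                     path, sep = "\t")
  invisible(path)
}
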