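#' Select the top genes behind a cohort's ranked features
#'
#' For node-based feature types the genes of the top `top_k_genes` ranked
#' features are taken directly (one gene per feature). For edge features,
#' ranked edges are walked in order and their endpoint genes inserted into an
#' ordered set; once the set reaches `top_k_genes` genes it is truncated to
#' the first `top_k_genes` in insertion order, so the result always has
#' exactly `top_k_genes` genes.
#'
#' @param table A `SignificanceTable`.
#' @param ftype The feature type the table was computed from.
#' @param top_k_genes Number of genes to select (default 160).
#' @return Character vector of exactly `top_k_genes` gene ids.
#' @export
select_top_genes <- function(table, ftype, top_k_genes = 160) {
  parsed <- .parse_ftype(ftype)
  if (parsed$op != "Edge") {
    if (nrow(table) < top_k_genes)
      stop("only ", nrow(table), " features available; need ", top_k_genes)
    return(rank_features(table, top_k_genes))
  }
  ranked <- rank_features(table, nrow(table))
  genes <- character(0)
  for (fid in ranked) {
    endpoints <- strsplit(fid, "|", fixed = TRUE)[[1]]
    genes <- c(genes, setdiff(endpoints, genes))
    if (length(genes) >= top_k_genes) break
  }
  if (length(genes) < top_k_genes)
    stop("edge universe too small: pooled only ", length(genes),
         " genes, need ", top_k_genes)
  genes[seq_len(top_k_genes)]
}

#' Overlap fold change between two cohorts' top gene sets
#'
#' The observed overlap of two equally sized gene sets is compared to the
#' overlap expected under independent random selection from a common
#' universe, k^2 / N (kept at full precision). A zero observed overlap is
#' replaced by a pseudocount before division so the fold change stays
#' defined on a log scale.
#'
#' @param set_a,set_b Character vectors of gene ids, equal length.
#' @param universe_size Size N of the gene universe both sets were drawn
#'   from.
#' @param pseudocount Floor applied to the observed overlap (default 0.5).
#' @return A list with `observed`, `expected`, `fold`.
#' @export
overlap_fold_change <- function(set_a, set_b, universe_size, pseudocount = 0.5) {
  if (length(set_a) != length(set_b))
    stop("gene sets differ in size (", length(set_a), " vs ", length(set_b), ")")
  if (anyDuplicated(set_a) || anyDuplicated(set_b))
    stop("gene sets must not contain duplicates")
  k <- length(set_a)
  observed <- length(intersect(set_a, set_b))
  expected <- k^2 / universe_size
  list(observed = observed,
       expected = expected,
       fold = max(observed, pseudocount) / expected)
}

#' Cross-cohort robustness summary for one feature type
#'
#' Evaluates the overlap fold change for every unordered pair of cohorts'
#' top gene sets and summarizes with the geometric mean of the fold changes.
#' Per-cohort degree diagnostics (mean and median network degree of the
#' selected genes) expose the hub bias that can inflate apparent overlap of
#' edge-derived signatures.
#'
#' @param per_cohort_sets Named list mapping cohort id to its selected gene
#'   set (equal sizes).
#' @param universe_size Gene universe size N.
#' @param network Optional `GeneNetwork` for degree diagnostics.
#' @param pseudocount Passed to [overlap_fold_change()].
#' @return A `RobustnessResult`: list with `pairwise` (data.frame cohort_a,
#'   cohort_b, observed, expected, fold), `geometric_mean_fold`, and
#'   `degree_diag` (data.frame cohort, mean_degree, median_degree; NULL when
#'   no network is given).
#' @export
robustness_summary <- function(per_cohort_sets, universe_size, network = NULL,
                               pseudocount = 0.5) {
  if (length(per_cohort_sets) < 2) stop("need >= 2 cohorts")
  cohorts <- names(per_cohort_sets)
  if (is.null(cohorts)) stop("per_cohort_sets must be named by cohort")
  pairs <- utils::combn(cohorts, 2)
  pw <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    o <- overlap_fold_change(per_cohort_sets[[a]], per_cohort_sets[[b]],
                             universe_size, pseudocount)
    data.frame(cohort_a = a, cohort_b = b, observed = o$observed,
               expected = o$expected, fold = o$fold,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  geo <- exp(mean(log(pw$fold)))
  diag <- NULL
  if (!is.null(network)) {
    diag <- do.call(rbind, lapply(cohorts, function(cc) {
      s <- degree_summary(network, per_cohort_sets[[cc]])
      data.frame(cohort = cc, mean_degree = s$mean_degree,
                 median_degree = s$median_degree, stringsAsFactors = FALSE)
    }))
  }
  structure(list(pairwise = pw, geometric_mean_fold = geo,
                 degree_diag = diag),
            class = "RobustnessResult")
}

#' @export
print.RobustnessResult <- function(x, ...) {
  cat(sprintf("RobustnessResult: %d cohort pairs, geometric mean fold = %.3f\n",
              nrow(x$pairwise), x$geometric_mean_fold))
  invisible(x)
}

#' Per-cohort top-gene sets for one feature type
#'
#' Convenience wrapper: splits a labelled multi-cohort dataset by cohort,
#' computes the feature matrix and significance table within each cohort
#' independently, and selects each cohort's top genes.
#'
#' @param dataset A labelled multi-cohort `ExpressionDataset`.
#' @param ftype One of [feature_types()].
#' @param network `GeneNetwork` for network-based types (ignored for Gene).
#' @param top_k_genes Genes to select per cohort (default 160).
#' @return Named list of gene-id vectors, one per cohort.
#' @export
per_cohort_top_genes <- function(dataset, ftype, network = NULL,
                                 top_k_genes = 160) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (is.null(dataset$cohort)) stop("dataset has no cohort labels")
  cohorts <- unique(dataset$cohort)
  sets <- lapply(cohorts, function(cc) {
    sub <- subset_patients(dataset, dataset$patient_ids[dataset$cohort == cc])
    fm <- compute_features(sub, ftype, network)
    tab <- suppressWarnings(feature_significance(fm, sub))
    select_top_genes(tab, ftype, top_k_genes)
  })
  stats::setNames(sets, cohorts)
}

#' Write a robustness report to TSV
#'
#' @param result A `RobustnessResult`.
#' @param path Output path for the pairwise table; a `summary` sidecar file
#'   receives the geometric mean and degree diagnostics.
#' @param feature_type Feature type label echoed into the tables.
#' @return `path`, invisibly.
#' @export
write_robustness <- function(result, path, feature_type = NA_character_) {
  pw <- cbind(feature_type = feature_type, result$pairwise)
  data.table::fwrite(pw, path, sep = "\t")
  lines <- sprintf("geometric_mean_fold\t%.6g", result$geometric_mean_fold)
  if (!is.null(result$degree_diag))
    lines <- c(lines, sprintf("degree\t%s\t%.4g\t%.4g",
                              result$degree_diag$cohort,
                              result$degree_diag$mean_degree,
                              result$degree_diag$median_degree))
  writeLines(lines, paste0(path, ".summary"))
  invisible(path)
}
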