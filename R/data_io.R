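#' Construct an expression dataset
#'
#' Bundles a genes x patients matrix of log-scale expression values with
#' per-patient binary outcome labels (poor = 1, good = 0) and cohort
#' assignments. Values are expected to be log-normalized and mean-centered
#' upstream; no normalization is performed here.
#'
#' @param values Numeric matrix, genes in rows and patients in columns, with
#'   unique rownames (gene ids) and colnames (patient ids). All entries must
#'   be finite; missing values are rejected, not imputed.
#' @param outcome Optional integer/numeric vector of 0 (good) / 1 (poor) per
#'   patient, in column order or named by patient id.
#' @param cohort Optional character vector of cohort ids per patient, in
#'   column order or named by patient id.
#' @param center_tol Warn if the global mean of `values` deviates from 0 by
#'   more than this tolerance (the pipeline assumes mean-centered input).
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `outcome`, `cohort`, `gene_ids`, `patient_ids`.
#' @export
expression_dataset <- function(values, outcome = NULL, cohort = NULL,
                               center_tol = 0.1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  gene_ids <- rownames(values)
  patient_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(patient_ids))
    stop("'values' must have rownames (gene ids) and colnames (patient ids)")
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_p <- patient_ids[duplicated(patient_ids)]
  if (length(dup_p))
    stop("duplicate patient id(s): ", paste(unique(dup_p), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite (missing/NA/Inf rejected)")
  if (is.finite(center_tol) && abs(mean(values)) > center_tol)
    warning(sprintf(
      "global mean of expression values is %.4f; input is expected to be mean-centered",
      mean(values)))

  align <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (!is.null(names(x))) {
      missing <- setdiff(patient_ids, names(x))
      if (length(missing))
        stop(what, " missing for patient(s): ", paste(missing, collapse = ", "))
      x <- x[patient_ids]
    } else if (length(x) != length(patient_ids)) {
      stop(what, " must have one entry per patient")
    }
    stats::setNames(x, patient_ids)
  }
  outcome <- align(outcome, "outcome")
  if (!is.null(outcome)) {
    if (!all(outcome %in% c(0L, 1L)))
      stop("outcome must be coded 0 (good) / 1 (poor)")
    outcome <- as.integer(outcome)
    names(outcome) <- patient_ids
  }
  cohort <- align(cohort, "cohort")
  if (!is.null(cohort)) cohort <- stats::setNames(as.character(cohort), patient_ids)

  structure(
    list(values = values, outcome = outcome, cohort = cohort,
         gene_ids = gene_ids, patient_ids = patient_ids),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d patients\n",
              length(x$gene_ids), length(x$patient_ids)))
  if (!is.null(x$outcome))
    cat(sprintf("  outcome: %d poor / %d good\n",
                sum(x$outcome == 1L), sum(x$outcome == 0L)))
  if (!is.null(x$cohort))
    cat(sprintf("  cohorts: %s\n", paste(unique(x$cohort), collapse = ", ")))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header row holds patient ids; the body must be numeric. Row and column
#' order are preserved.
#'
#' @param path Path to the TSV file.
#' @param center_tol Passed to [expression_dataset()].
#' @return An `ExpressionDataset` with values only; join labels with
#'   [join_phenotype()].
#' @export
read_expression <- function(path, center_tol = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = TRUE)
  if (ncol(dt) < 2) stop("expression file needs a gene-id column and >= 1 patient column")
  gene_ids <- dt[[1]]
  body <- dt[, -1, with = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1]
      stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                   if (is.na(bad)) which(is.na(col))[1] else bad,
                   names(body)[j], path))
    }
    if (anyNA(col))
      stop(sprintf("missing value at row %d, column '%s' in %s",
                   which(is.na(col))[1], names(body)[j], path))
  }
  values <- as.matrix(body)
  rownames(values) <- gene_ids
  expression_dataset(values, center_tol = center_tol)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: first column `gene_id`, one column per
#' patient, tab-separated, '.' decimal.
#'
#' @param dataset An `ExpressionDataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  dt <- data.table::data.table(gene_id = dataset$gene_ids)
  dt <- cbind(dt, data.table::as.data.table(dataset$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' Columns: `patient_id`, `outcome` (good/poor, case-insensitive), `cohort`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `patient_id`, `outcome` (0/1 coded,
#'   poor = 1), `cohort`.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  need <- c("patient_id", "outcome", "cohort")
  if (!all(need %in% names(dt)))
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  out <- tolower(dt$outcome)
  bad <- setdiff(unique(out), c("good", "poor"))
  if (length(bad))
    stop("outcome labels must be 'good' or 'poor'; found: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(dt$patient_id))
    stop("duplicate patient id(s) in phenotype table: ",
         paste(unique(dt$patient_id[duplicated(dt$patient_id)]), collapse = ", "))
  data.frame(patient_id = dt$patient_id,
             outcome = as.integer(out == "poor"),
             cohort = dt$cohort,
             stringsAsFactors = FALSE)
}

#' Write a phenotype table to TSV
#'
#' @param dataset A labelled `ExpressionDataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(dataset, path) {
  stopifnot(inherits(dataset, "ExpressionDataset"), !is.null(dataset$outcome))
  dt <- data.table::data.table(
    patient_id = dataset$patient_ids,
    outcome = ifelse(dataset$outcome == 1L, "poor", "good"),
    cohort = dataset$cohort)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Join outcome and cohort labels onto an expression dataset
#'
#' Labels are matched by patient id, not by position; phenotype rows for
#' patients absent from the matrix are ignored (a message reports how many).
#'
#' @param dataset An `ExpressionDataset`.
#' @param phenotype A data.frame as returned by [read_phenotype()] (columns
#'   `patient_id`, `outcome` coded 0/1 or good/poor, `cohort`).
#' @return The dataset with `outcome` and `cohort` populated.
#' @export
join_phenotype <- function(dataset, phenotype) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  need <- c("patient_id", "outcome", "cohort")
  if (!all(need %in% names(phenotype)))
    stop("phenotype must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(phenotype$patient_id))
    stop("duplicate patient id(s) in phenotype table")
  missing <- setdiff(dataset$patient_ids, phenotype$patient_id)
  if (length(missing))
    stop("patients missing from phenotype table: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(phenotype$patient_id, dataset$patient_ids)
  if (length(extra))
    message(length(extra), " phenotype row(s) for patients not in the matrix were ignored")
  idx <- match(dataset$patient_ids, phenotype$patient_id)
  out <- phenotype$outcome[idx]
  if (is.character(out)) out <- as.integer(tolower(out) == "poor")
  expression_dataset(dataset$values,
                     outcome = as.integer(out),
                     cohort = as.character(phenotype$cohort[idx]),
                     center_tol = Inf)
}

#' Subset an expression dataset by patients
#'
#' @param dataset An `ExpressionDataset`.
#' @param patient_ids Patient ids to keep (order respected).
#' @return The subsetted `ExpressionDataset`.
#' @export
subset_patients <- function(dataset, patient_ids) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  missing <- setdiff(patient_ids, dataset$patient_ids)
  if (length(missing))
    stop("unknown patient id(s): ", paste(missing, collapse = ", "))
  expression_dataset(dataset$values[, patient_ids, drop = FALSE],
                     outcome = if (!is.null(dataset$outcome)) dataset$outcome[patient_ids],
                     cohort = if (!is.null(dataset$cohort)) dataset$cohort[patient_ids],
                     center_tol = Inf)
}
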