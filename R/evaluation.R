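#' Area under the ROC curve
#'
#' Rank-statistic definition: the probability that a uniformly random
#' positive (poor outcome) patient is scored above a uniformly random
#' negative one, with ties credited 0.5. Equivalent to the Mann-Whitney U
#' statistic divided by n1 * n0.
#'
#' @param scores Numeric vector of per-patient scores (higher = more likely
#'   poor outcome).
#' @param labels Binary 0/1 outcome vector.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)                      # midranks handle ties as 0.5 credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified cross-validation fold assignment
#'
#' Patients are shuffled within each class and dealt round-robin into folds,
#' so every fold contains both classes whenever each class has at least
#' `n_folds` members. Fully determined by the seed.
#'
#' @param labels Binary 0/1 outcome vector.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @param stratified Stratify by class (default TRUE).
#' @return Integer vector of fold ids (1..n_folds), one per patient.
#' @export
make_folds <- function(labels, n_folds = 5, seed = 1, stratified = TRUE) {
  n <- length(labels)
  if (n_folds < 2) stop("n_folds must be >= 2")
  set.seed(seed)
  folds <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds)
        stop("class ", cl, " has fewer members (", length(idx),
             ") than folds (", n_folds, ")")
      folds[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    folds[sample(n)] <- rep_len(seq_len(n_folds), n)
  }
  folds
}

# Ridge-penalized logistic regression with training-only z-score
# standardization. C is the inverse regularization strength; the glmnet
# penalty is lambda = 1 / (n_train * C). Constant columns are zeroed after
# scaling. Returns a closure scoring new patients.
.fit_ridge_logistic <- function(x_train, y_train, C = 1.0,
                                maxit = 1e5, thresh = 1e-8) {
  ctr <- colMeans(x_train)
  scl <- apply(x_train, 2, stats::sd)
  scl[scl == 0] <- Inf                   # constant feature -> column of zeros
  xs <- sweep(sweep(x_train, 2, ctr), 2, scl, "/")
  pad <- ncol(xs) < 2
  if (pad) xs <- cbind(xs, .pad = 0)     # glmnet needs >= 2 columns
  lam <- 1 / (nrow(xs) * C)
  fit <- glmnet::glmnet(xs, y_train, family = "binomial", alpha = 0,
                        lambda = lam * c(1000, 100, 10, 1),
                        standardize = FALSE, maxit = maxit, thresh = thresh)
  function(x_new) {
    xn <- sweep(sweep(x_new, 2, ctr), 2, scl, "/")
    if (pad) xn <- cbind(xn, .pad = 0)
    as.numeric(stats::predict(fit, xn, s = lam, type = "response"))
  }
}

#' Repeated stratified cross-validation of one feature type
#'
#' For each repetition a fresh stratified fold assignment is drawn
#' (repetition r uses seed `seed + r - 1`). Within each fold, features are
#' z-score standardized on the training patients only, an L2-regularized
#' logistic regression is fit, held-out patients are scored, and the AUC of
#' the held-out scores is recorded.
#'
#' @param fm A `FeatureMatrix`.
#' @param outcome Binary 0/1 outcome vector aligned to the feature matrix's
#'   patient columns, or a labelled `ExpressionDataset`.
#' @param n_folds Folds per repetition (default 5).
#' @param n_repetitions Repetitions (default 10).
#' @param seed Integer master seed.
#' @param stratified Stratify folds by class (default TRUE).
#' @param C Inverse regularization strength of the logistic model
#'   (default 1.0).
#' @return An `EvaluationResult`: list with `feature_type`, `per_fold_auc`
#'   (repetitions x folds matrix), `mean_auc`, and the configuration used.
#' @export
run_cv <- function(fm, outcome, n_folds = 5, n_repetitions = 10, seed = 1,
                   stratified = TRUE, C = 1.0) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  if (inherits(outcome, "ExpressionDataset"))
    outcome <- outcome$outcome[colnames(fm$values)]
  .run_cv_matrix(t(fm$values), as.integer(outcome), fm$feature_type,
                 n_folds, n_repetitions, seed, stratified, C)
}

# CV engine on a patients x features matrix; run_cv and the subsample
# experiment share it so feature matrices can be computed once and
# column-subset per draw.
.run_cv_matrix <- function(x, outcome, feature_type, n_folds, n_repetitions,
                           seed, stratified, C) {
  aucs <- matrix(NA_real_, n_repetitions, n_folds,
                 dimnames = list(paste0("rep", seq_len(n_repetitions)),
                                 paste0("fold", seq_len(n_folds))))
  for (r in seq_len(n_repetitions)) {
    folds <- make_folds(outcome, n_folds, seed = seed + r - 1L,
                        stratified = stratified)
    for (f in seq_len(n_folds)) {
      test <- folds == f
      if (length(unique(outcome[test])) < 2)
        stop("fold ", f, " of repetition ", r, " contains a single class")
      model <- .fit_ridge_logistic(x[!test, , drop = FALSE], outcome[!test], C)
      aucs[r, f] <- auc(model(x[test, , drop = FALSE]), outcome[test])
    }
  }
  structure(list(feature_type = feature_type,
                 per_fold_auc = aucs,
                 mean_auc = mean(aucs),
                 config = list(n_folds = n_folds, n_repetitions = n_repetitions,
                               seed = seed, stratified = stratified, C = C)),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf("EvaluationResult [%s]: mean AUC %.4f over %d x %d CV\n",
              x$feature_type, x$mean_auc,
              nrow(x$per_fold_auc), ncol(x$per_fold_auc)))
  invisible(x)
}

#' Average component probabilities into a CNF prediction
#'
#' The combined network features (CNF) ensemble averages the predicted
#' probabilities of eight logistic models, one per component feature type
#' (MEAN, MAX, MIN, MED for both the co-expression and the PPI network).
#'
#' @param component_probabilities Named list of eight numeric probability
#'   vectors (names must be [cnf_component_types()]), equal lengths, entries
#'   in \[0, 1\].
#' @return Numeric vector: the elementwise arithmetic mean.
#' @export
cnf_predict <- function(component_probabilities) {
  expected <- cnf_component_types()
  if (!is.list(component_probabilities) ||
      !setequal(names(component_probabilities), expected) ||
      length(component_probabilities) != length(expected))
    stop("CNF requires exactly the 8 components: ",
         paste(expected, collapse = ", "))
  lens <- lengths(component_probabilities)
  if (length(unique(lens)) != 1)
    stop("component probability vectors differ in length")
  m <- do.call(cbind, component_probabilities[expected])
  if (any(!is.finite(m)) || any(m < 0 | m > 1))
    stop("probabilities must lie in [0, 1]")
  rowMeans(m)
}

#' Repeated cross-validation of the CNF ensemble
#'
#' Within each repetition all eight component models share one fold
#' assignment (the same assignment [run_cv()] would draw for that seed and
#' repetition), so each held-out patient receives eight probabilities from
#' models trained on identical training folds; the AUC is computed on their
#' average.
#'
#' @param dataset A labelled `ExpressionDataset`.
#' @param ce_network Co-expression `GeneNetwork`.
#' @param ppi_network Interaction `GeneNetwork`.
#' @param n_folds,n_repetitions,seed,stratified,C As in [run_cv()].
#' @return An `EvaluationResult` with `feature_type = "CNF"`.
#' @export
run_cnf_cv <- function(dataset, ce_network, ppi_network,
                       n_folds = 5, n_repetitions = 10, seed = 1,
                       stratified = TRUE, C = 1.0) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (is.null(dataset$outcome)) stop("dataset has no outcome labels")
  comps <- cnf_component_types()
  mats <- lapply(comps, function(ft) {
    net <- if (startsWith(ft, "PPI")) ppi_network else ce_network
    t(compute_features(dataset, ft, net)$values)
  })
  names(mats) <- comps
  .run_cnf_cv_mats(mats, dataset$outcome, n_folds, n_repetitions, seed,
                   stratified, C)
}

# CNF CV engine on precomputed patients x features component matrices.
.run_cnf_cv_mats <- function(mats, outcome, n_folds, n_repetitions, seed,
                             stratified, C) {
  aucs <- matrix(NA_real_, n_repetitions, n_folds,
                 dimnames = list(paste0("rep", seq_len(n_repetitions)),
                                 paste0("fold", seq_len(n_folds))))
  for (r in seq_len(n_repetitions)) {
    folds <- make_folds(outcome, n_folds, seed = seed + r - 1L,
                        stratified = stratified)
    for (f in seq_len(n_folds)) {
      test <- folds == f
      if (length(unique(outcome[test])) < 2)
        stop("fold ", f, " of repetition ", r, " contains a single class")
      probs <- lapply(mats, function(x) {
        model <- .fit_ridge_logistic(x[!test, , drop = FALSE], outcome[!test], C)
        model(x[test, , drop = FALSE])
      })
      aucs[r, f] <- auc(cnf_predict(probs), outcome[test])
    }
  }
  structure(list(feature_type = "CNF",
                 per_fold_auc = aucs,
                 mean_auc = mean(aucs),
                 config = list(n_folds = n_folds, n_repetitions = n_repetitions,
                               seed = seed, stratified = stratified, C = C)),
            class = "EvaluationResult")
}

#' Stratified subsample of a labelled dataset
#'
#' Draws `round(percentage * n_class)` patients per class without
#' replacement, preserving the class ratio to the nearest patient.
#'
#' @param dataset A labelled `ExpressionDataset`.
#' @param percentage Fraction of patients to keep, in (0, 1].
#' @param seed Integer seed.
#' @return The subsampled `ExpressionDataset`.
#' @export
draw_subsample <- function(dataset, percentage, seed = 1) {
  stopifnot(inherits(dataset, "ExpressionDataset"), !is.null(dataset$outcome))
  if (percentage <= 0 || percentage > 1) stop("percentage must be in (0, 1]")
  set.seed(seed)
  keep <- unlist(lapply(c(1L, 0L), function(cl) {
    ids <- dataset$patient_ids[dataset$outcome == cl]
    sample(ids, max(1L, round(percentage * length(ids))))
  }))
  subset_patients(dataset, dataset$patient_ids[dataset$patient_ids %in% keep])
}

#' Sample-size subsampling experiment
#'
#' For each percentage level, `n_subsamples` class-stratified subsamples are
#' drawn without replacement and each is evaluated with repeated
#' cross-validation for every requested feature type (and optionally the CNF
#' ensemble). Subsample s at percentage level i uses seed
#' `seed + 1000 * i + s`; the CV inside each subsample is seeded with the
#' same value.
#'
#' @param dataset A labelled `ExpressionDataset`.
#' @param ce_network,ppi_network `GeneNetwork`s used for network feature
#'   types and CNF.
#' @param ftypes Feature types to evaluate (default `"Gene"`).
#' @param include_cnf Also evaluate the CNF ensemble (default TRUE).
#' @param percentages Subsample fractions (default 0.9 down to 0.1 by 0.1).
#' @param n_subsamples Subsamples per level (default 10).
#' @param n_folds,n_repetitions,C As in [run_cv()].
#' @param seed Integer master seed.
#' @return A data.frame with columns `feature_type`, `percentage`,
#'   `subsample`, `mean_auc`.
#' @export
subsample_experiment <- function(dataset, ce_network = NULL, ppi_network = NULL,
                                 ftypes = "Gene", include_cnf = TRUE,
                                 percentages = seq(0.9, 0.1, by = -0.1),
                                 n_subsamples = 10, n_folds = 5,
                                 n_repetitions = 10, C = 1.0, seed = 1) {
  stopifnot(inherits(dataset, "ExpressionDataset"), !is.null(dataset$outcome))
  n1 <- sum(dataset$outcome == 1L); n0 <- sum(dataset$outcome == 0L)
  too_small <- percentages[round(percentages * pmin(n1, n0)) < n_folds]
  if (length(too_small))
    stop("percentage(s) too small for ", n_folds, "-fold stratified CV: ",
         paste(too_small, collapse = ", "))
  # features are per-patient independent, so compute each matrix once on the
  # full dataset and subset patient rows per draw
  net_for <- function(ft) {
    if (ft == "Gene") NULL
    else if (startsWith(ft, "PPI")) ppi_network else ce_network
  }
  fmats <- lapply(ftypes, function(ft)
    t(compute_features(dataset, ft, net_for(ft))$values))
  names(fmats) <- ftypes
  cmats <- NULL
  if (include_cnf) {
    comps <- cnf_component_types()
    cmats <- lapply(comps, function(ft)
      t(compute_features(dataset, ft, net_for(ft))$values))
    names(cmats) <- comps
  }
  rows <- list()
  for (i in seq_along(percentages)) {
    p <- percentages[i]
    for (s in seq_len(n_subsamples)) {
      sub_seed <- seed + 1000L * i + s
      sub <- draw_subsample(dataset, p, seed = sub_seed)
      pid <- sub$patient_ids
      y <- sub$outcome
      for (ft in ftypes) {
        res <- .run_cv_matrix(fmats[[ft]][pid, , drop = FALSE], y, ft,
                              n_folds, n_repetitions, sub_seed, TRUE, C)
        rows[[length(rows) + 1L]] <-
          data.frame(feature_type = ft, percentage = p, subsample = s,
                     mean_auc = res$mean_auc, stringsAsFactors = FALSE)
      }
      if (include_cnf) {
        res <- .run_cnf_cv_mats(lapply(cmats, function(m) m[pid, , drop = FALSE]),
                                y, n_folds, n_repetitions, sub_seed, TRUE, C)
        rows[[length(rows) + 1L]] <-
          data.frame(feature_type = "CNF", percentage = p, subsample = s,
                     mean_auc = res$mean_auc, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write an evaluation result to TSV
#'
#' Long format: feature_type, repetition, fold, auc.
#'
#' @param result An `EvaluationResult`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(result, path) {
  m <- result$per_fold_auc
  dt <- data.table::data.table(
    feature_type = result$feature_type,
    repetition = rep(seq_len(nrow(m)), ncol(m)),
    fold = rep(seq_len(ncol(m)), each = nrow(m)),
    auc = as.vector(m))
  data.table::fwrite(dt[order(dt$repetition, dt$fold), ], path, sep = "\t")
  invisible(path)
}
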