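test_that("AUC is the tie-aware rank statistic", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("stratified folds contain both classes and are seed-reproducible", {
  y <- rep(c(1L, 0L), c(12, 28))
  f1 <- make_folds(y, 5, seed = 3)
  f2 <- make_folds(y, 5, seed = 3)
  expect_identical(f1, f2)
  for (k in 1:5) expect_setequal(unique(y[f1 == k]), c(0L, 1L))
  expect_error(make_folds(rep(c(1L, 0L), c(3, 30)), 5), "fewer members")
})

test_that("repeated CV returns the full repetition x fold grid, reproducibly", {
  toy <- toy_feature_matrix(informative = TRUE)
  r1 <- run_cv(toy$fm, toy$outcome, n_folds = 5, n_repetitions = 10, seed = 2)
  expect_identical(dim(r1$per_fold_auc), c(10L, 5L))
  expect_equal(r1$mean_auc, mean(r1$per_fold_auc))
  expect_gt(r1$mean_auc, 0.8)    # planted signal is recoverable
  r2 <- run_cv(toy$fm, toy$outcome, n_folds = 5, n_repetitions = 10, seed = 2)
  expect_identical(r1$per_fold_auc, r2$per_fold_auc)
})

test_that("CV AUC on label-independent features centers on 0.5", {
  aucs <- sapply(1:20, function(s) {
    toy <- toy_feature_matrix(n_features = 20, n_patients = 300, seed = s)
    run_cv(toy$fm, toy$outcome, n_repetitions = 1, seed = s)$mean_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("standardization statistics come from training folds only", {
  set.seed(4)
  xtr <- matrix(rnorm(200), 40, 5)
  ytr <- rep(c(0L, 1L), 20)
  model <- netfeat:::.fit_ridge_logistic(xtr, ytr)
  xte <- matrix(rnorm(10), 2, 5)
  alone <- model(xte[1, , drop = FALSE])
  with_outlier <- model(rbind(xte[1, ], 1e3 * xte[2, ]))[1]
  expect_equal(alone, with_outlier)
})

test_that("CNF averaging is the elementwise mean with strict validation", {
  comps <- setNames(rep(list(c(0.2, 0.7)), 8), cnf_component_types())
  expect_equal(cnf_predict(comps), c(0.2, 0.7))

  vals <- c(0.2, 0.4, 0.6, 0.8, 0.2, 0.4, 0.6, 0.8)
  comps2 <- setNames(lapply(vals, function(v) v), cnf_component_types())
  expect_equal(cnf_predict(comps2), 0.5)

  bad_len <- comps; bad_len[[1]] <- 0.5
  expect_error(cnf_predict(bad_len), "length")
  bad_range <- comps; bad_range[[2]] <- c(0.1, 1.3)
  expect_error(cnf_predict(bad_range), "\\[0, 1\\]")
  expect_error(cnf_predict(comps[1:7]), "8 components")
  wrong_names <- setNames(comps, c(cnf_component_types()[-1], "Gene"))
  expect_error(cnf_predict(wrong_names), "8 components")
})

test_that("CNF on edgeless networks reduces exactly to the single gene model", {
  set.seed(6)
  y <- rep(c(1L, 0L), each = 20)
  v <- matrix(rnorm(8 * 40), 8, 40,
              dimnames = list(sprintf("g%02d", 1:8), sprintf("p%02d", 1:40)))
  v[1, ] <- v[1, ] + 1.5 * y
  d <- expression_dataset(v, outcome = y, center_tol = Inf)
  empty <- gene_network(d$gene_ids)
  cnf <- run_cnf_cv(d, empty, empty, n_repetitions = 3, seed = 11)
  gene <- run_cv(compute_features(d, "Gene"), d, n_repetitions = 3, seed = 11)
  expect_equal(cnf$per_fold_auc, gene$per_fold_auc)
})

test_that("the subsample experiment covers the grid and respects preconditions", {
  st <- generate_study(simulation_config(
    n_genes = 40, module_size = 10, n_modules_differential = 2,
    cohorts = data.frame(study = "c1", n_poor = 60, n_good = 90), seed = 14))
  d <- st$dataset
  net <- st$true_network
  res <- subsample_experiment(d, net, net, ftypes = "Gene", include_cnf = FALSE,
                              percentages = c(0.9, 0.5), n_subsamples = 2,
                              n_repetitions = 1, seed = 5)
  expect_identical(nrow(res), 4L)
  expect_setequal(unique(res$percentage), c(0.9, 0.5))

  expect_error(subsample_experiment(d, net, net, percentages = 0.01,
                                    n_subsamples = 1, n_repetitions = 1),
               "too small")

  # percentage 1.0 with one subsample equals evaluating the full dataset
  res1 <- subsample_experiment(d, net, net, ftypes = "Gene",
                               include_cnf = FALSE, percentages = 1,
                               n_subsamples = 1, n_repetitions = 1, seed = 5)
  full <- run_cv(compute_features(d, "Gene"), d, n_repetitions = 1,
                 seed = 5 + 1000L + 1L)
  expect_equal(res1$mean_auc, full$mean_auc)
})

test_that("evaluation results serialize to the long TSV format", {
  toy <- toy_feature_matrix()
  res <- run_cv(toy$fm, toy$outcome, n_folds = 3, n_repetitions = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_evaluation(res, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 6L)
  expect_equal(mean(tab$auc), res$mean_auc)
})
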