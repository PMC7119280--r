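sig_table <- function(ids, p) {
  data.frame(feature_id = ids, t_stat = 0, p_value = p,
             p_adjusted = p, rank = rank(p, ties.method = "first"))
}

test_that("node-based selection takes the genes of the top-ranked features", {
  ids <- sprintf("g%03d", 1:200)
  p <- seq(0.001, 0.2, length.out = 200)
  tab <- sig_table(ids, p)
  sel <- select_top_genes(tab, "Gene", 160)
  expect_identical(sel, ids[1:160])
  expect_error(select_top_genes(sig_table(ids[1:100], p[1:100]), "Gene", 160),
               "only 100")
})

test_that("edge pooling inserts endpoints in rank order and truncates", {
  tab <- sig_table(c("a|b", "b|c", "d|e"), c(0.01, 0.02, 0.03))
  expect_identical(select_top_genes(tab, "CEEdge", 4), c("a", "b", "c", "d"))
})

test_that("edge pooling satisfies the replay property on random rankings", {
  set.seed(31)
  genes <- sprintf("g%02d", 1:40)
  pairs <- t(combn(genes, 2))
  for (i in 1:5) {
    e <- pairs[sample(nrow(pairs), 120), ]
    ids <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "|")
    ids <- unique(ids)
    tab <- sig_table(ids, seq_along(ids) / (2 * length(ids)))
    k <- 25
    sel <- select_top_genes(tab, "PPIEdge", k)
    expect_length(sel, k)
    expect_identical(anyDuplicated(sel), 0L)
    # replay: every selected gene appears in an edge ranked no worse than
    # the first edge at which the pooled set reached k genes
    ranked <- rank_features(tab, nrow(tab))
    pooled <- character(0); last <- 0L
    for (j in seq_along(ranked)) {
      pooled <- union(pooled, strsplit(ranked[j], "|", fixed = TRUE)[[1]])
      if (length(pooled) >= k) { last <- j; break }
    }
    early_genes <- unique(unlist(strsplit(ranked[seq_len(last)], "|", fixed = TRUE)))
    expect_true(all(sel %in% early_genes))
  }
})

test_that("overlap fold change follows the k^2/N expectation", {
  s <- sprintf("g%05d", 1:160)
  r <- overlap_fold_change(s, s, universe_size = 12750)
  expect_identical(r$observed, 160L)
  expect_equal(r$expected, 160^2 / 12750)
  expect_equal(r$fold, 12750 / 160)       # = 79.6875

  r0 <- overlap_fold_change(sprintf("a%03d", 1:50), sprintf("b%03d", 1:50),
                            universe_size = 1000)
  expect_identical(r0$observed, 0L)
  expect_equal(r0$fold, 0.5 / (50^2 / 1000))

  expect_error(overlap_fold_change(s[1:10], s[1:9], 100), "differ in size")
})

test_that("mean observed overlap of independent draws matches k^2/N", {
  set.seed(17)
  N <- 12750; k <- 160
  obs <- replicate(3000, {
    length(intersect(sample.int(N, k), sample.int(N, k)))
  })
  expect_equal(mean(obs), k^2 / N, tolerance = 0.05)
})

test_that("robustness summaries enumerate all cohort pairs", {
  sets <- setNames(lapply(1:12, function(i) sprintf("g%05d", 1:160)),
                   paste0("cohort", 1:12))
  res <- robustness_summary(sets, universe_size = 12750)
  expect_identical(nrow(res$pairwise), 66L)
  expect_equal(res$geometric_mean_fold, 12750 / 160)

  two <- robustness_summary(sets[1:2], universe_size = 12750)
  expect_identical(nrow(two$pairwise), 1L)
  expect_equal(two$geometric_mean_fold, two$pairwise$fold[1])
  expect_error(robustness_summary(sets[1], 12750), ">= 2 cohorts")
})

test_that("the geometric mean is invariant to cohort relabeling", {
  set.seed(41)
  sets <- setNames(lapply(1:4, function(i) sample(sprintf("g%03d", 1:500), 50)),
                   paste0("c", 1:4))
  a <- robustness_summary(sets, 500)$geometric_mean_fold
  b <- robustness_summary(rev(sets), 500)$geometric_mean_fold
  expect_equal(a, b)
})

test_that("top edge-feature genes are hub-biased on synthetic data", {
  for (seed in 1:3) {
    st <- generate_study(simulation_config(n_genes = 400,
                                           n_modules_differential = 8,
                                           seed = seed))
    ce <- build_mutual_knn(st$dataset, 12)
    fm <- compute_features(st$dataset, "CEEdge", ce)
    tab <- suppressWarnings(feature_significance(fm, st$dataset))
    top <- select_top_genes(tab, "CEEdge", 100)
    expect_gt(degree_summary(ce, top)$mean_degree,
              degree_summary(ce)$mean_degree)
  }
})

test_that("per-cohort selection pipelines through features and significance", {
  st <- generate_study(simulation_config(n_genes = 60, module_size = 10,
                                         n_modules_differential = 2,
                                         cohorts = data.frame(
                                           study = c("c1", "c2"),
                                           n_poor = c(20, 25),
                                           n_good = c(30, 35)),
                                         seed = 8))
  sets <- per_cohort_top_genes(st$dataset, "PPIMEAN", st$true_network,
                               top_k_genes = 15)
  expect_identical(names(sets), c("c1", "c2"))
  expect_true(all(lengths(sets) == 15))
  res <- robustness_summary(sets, 60, network = st$true_network)
  expect_identical(nrow(res$pairwise), 1L)
  expect_identical(nrow(res$degree_diag), 2L)
})
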