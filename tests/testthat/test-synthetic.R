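test_that("the generator is deterministic and honors its config exactly", {
  cfg <- simulation_config(n_genes = 50, module_size = 5,
                           n_modules_differential = 3, seed = 22)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$dataset$outcome, b$dataset$outcome)

  d <- a$dataset
  co <- cfg$cohorts
  expect_identical(as.integer(table(d$cohort)[co$study]),
                   as.integer(co$n_poor + co$n_good))
  expect_length(a$differential_genes, 3 * 5)
  expect_true(all(abs(rowMeans(d$values)) < 1e-12))  # per-gene centering
  # true network is a clique per module: every node has degree module_size-1
  expect_true(all(network_degree(a$true_network) == 4L))
})

test_that("config invariants are checked before sampling", {
  expect_error(simulation_config(n_genes = 55, module_size = 10), "divisible")
  expect_error(simulation_config(n_genes = 20, module_size = 10,
                                 n_modules_differential = 3), "exceeds")
  expect_error(simulation_config(noise_sd = -1), ">= 0")
})

test_that("with zero effect size per-gene p-values are approximately uniform", {
  fracs <- sapply(1:20, function(s) {
    st <- generate_study(simulation_config(
      n_genes = 200, module_size = 10, n_modules_differential = 0,
      effect_size = 0,
      cohorts = data.frame(study = "c1", n_poor = 40, n_good = 60),
      seed = 300 + s))
    p <- row_t_test(st$dataset$values, st$dataset$outcome)$p_value
    mean(p < 0.05)
  })
  # 200 genes x 20 seeds; module correlation leaves the mean near 0.05
  expect_lt(abs(mean(fracs) - 0.05), 0.015)
})

test_that("module structure shows up as within- vs between-module correlation", {
  st <- generate_study(simulation_config(
    n_genes = 100, module_size = 10, n_modules_differential = 0,
    effect_size = 0, gene_loading = 1, noise_sd = 1, batch_sd = 0,
    cohorts = data.frame(study = "c1", n_poor = 50, n_good = 50), seed = 77))
  C <- cor(t(st$dataset$values))
  module <- rep(1:10, each = 10)
  same <- outer(module, module, "==") & upper.tri(C)
  diff <- outer(module, module, "!=") & upper.tri(C)
  expect_gt(mean(C[same]), mean(C[diff]) + 0.3)
  # loading 1, noise 1: within-module correlation targets 1/(1+1) = 0.5
  expect_lt(abs(mean(C[same]) - 0.5), 0.05)
})

test_that("the 12-cohort default reproduces the reference totals and scales down", {
  tab <- aces_cohort_table()
  expect_identical(nrow(tab), 12L)
  expect_identical(sum(tab$n_poor), 455L)
  expect_identical(sum(tab$n_good), 1161L)
  expect_identical(sum(tab$n_total), 1616L)

  st <- generate_multi_cohort_like_table1(scale = 0.1, n_genes = 20,
                                          module_size = 10,
                                          n_modules_differential = 1, seed = 1)
  d <- st$dataset
  expect_identical(length(unique(d$cohort)), 12L)
  expect_lte(abs(length(d$patient_ids) - round(0.1 * 1616)), 3)
  # per-cohort class ratios match the reference within rounding
  co <- st$config$cohorts
  for (i in seq_len(12)) {
    ref_ratio <- tab$n_poor[i] / tab$n_total[i]
    got_ratio <- co$n_poor[i] / (co$n_poor[i] + co$n_good[i])
    expect_lt(abs(got_ratio - ref_ratio), 0.5 / (co$n_poor[i] + co$n_good[i]) + 0.06)
  }
})

test_that("top MEAN features on the true network recover differential modules", {
  st <- generate_study(simulation_config(
    n_genes = 2000, module_size = 10, n_modules_differential = 20,
    effect_size = 1.0,
    cohorts = data.frame(study = c("c1", "c2"), n_poor = c(150, 150),
                         n_good = c(350, 350)),
    seed = 9))
  fm <- compute_features(st$dataset, "PPIMEAN", st$true_network)
  tab <- suppressWarnings(feature_significance(fm, st$dataset))
  top <- select_top_genes(tab, "PPIMEAN", 160)
  observed <- length(intersect(top, st$differential_genes))
  expected <- 160 * length(st$differential_genes) / 2000
  expect_gt(observed / expected, 3)   # enrichment far beyond chance
})

test_that("single-gene mode plants signal without geneset structure", {
  st <- generate_study(simulation_config(
    n_genes = 100, module_size = 10, n_modules_differential = 2,
    effect_size = 2, signal_mode = "single_gene",
    cohorts = data.frame(study = "c1", n_poor = 80, n_good = 120),
    seed = 15))
  p <- row_t_test(st$dataset$values, st$dataset$outcome)$p_value
  is_diff <- st$dataset$gene_ids %in% st$differential_genes
  expect_lt(median(p[is_diff]), 0.01)
  expect_gt(median(p[!is_diff]), 0.1)
})

test_that("a study round-trips through its on-disk representation", {
  st <- generate_study(simulation_config(n_genes = 20, module_size = 5,
                                         n_modules_differential = 1,
                                         cohorts = data.frame(
                                           study = c("x", "y"),
                                           n_poor = c(5, 6), n_good = c(7, 8)),
                                         seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  d <- join_phenotype(read_expression(paths["expression"], center_tol = Inf),
                      read_phenotype(paths["phenotype"]))
  expect_equal(d$values, st$dataset$values, tolerance = 1e-12)
  expect_identical(d$outcome, st$dataset$outcome)
  net <- load_edge_list(paths["network"], d$gene_ids)
  expect_identical(network_edges(net), network_edges(st$true_network))
  expect_identical(readLines(paths["truth"]), st$differential_genes)
})
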