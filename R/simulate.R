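#' Reference cohort table for the simulator
#'
#' The twelve breast-cancer study cohorts whose sizes and class imbalance
#' the multi-cohort generator emulates: per-study counts of poor-outcome
#' (relapse within 5 years) and good-outcome (recurrence-free >= 5 years)
#' patients, totalling 455 poor and 1,161 good over 1,616 patients.
#'
#' @return A data.frame with columns `study`, `n_poor`, `n_good`, `n_total`.
#' @export
aces_cohort_table <- function() {
  tab <- data.frame(
    study  = c("Desmedt", "Hatzis", "Ivshina", "Loi", "Pawitan", "Miller",
               "Minn", "Schmidt", "Symmans", "WangY", "WangYE", "Zhang"),
    n_poor = c(56L, 102L, 30L, 24L, 33L, 21L, 21L, 24L, 37L, 10L, 88L, 9L),
    n_good = c(127L, 48L, 72L, 33L, 114L, 68L, 44L, 145L, 187L, 42L, 169L, 112L),
    stringsAsFactors = FALSE)
  tab$n_total <- tab$n_poor + tab$n_good
  tab
}

#' Simulation configuration
#'
#' Parameters of the multi-cohort expression generator. Genes are organized
#' into equally sized modules; each patient has one latent activity per
#' module, and in differential modules that activity is shifted by +/-
#' `effect_size`/2 according to outcome class. A gene's value is its
#' module's activity scaled by `gene_loading`, plus a per-cohort per-gene
#' batch offset and independent residual noise; the matrix is mean-centered
#' per gene after generation. Signal therefore lives in genesets (weak per
#' gene), which is the regime network-aggregated features are designed for;
#' `signal_mode = "single_gene"` instead shifts differential genes directly
#' with unshifted latents, planting gene-level signal without geneset
#' structure.
#'
#' @param n_genes Number of genes (divisible by `module_size`).
#' @param module_size Genes per module (default 10).
#' @param n_modules_differential Number of class-associated modules.
#' @param effect_size Class shift delta of a differential module's latent
#'   activity, in latent-SD units (default 1.0).
#' @param gene_loading Weight lambda of the module activity in each gene
#'   (default 0.4), so the per-gene class effect is `gene_loading *
#'   effect_size` against residual noise of SD `noise_sd` -- individually
#'   weak genes whose module carries a usable signal.
#' @param noise_sd Per-gene residual SD (default 1.0).
#' @param cohorts Data.frame with columns `study`, `n_poor`, `n_good` (one
#'   row per cohort).
#' @param batch_sd SD of the per-cohort per-gene offset (default 0.3).
#' @param signal_mode `"module"` (default) or `"single_gene"`.
#' @param seed Integer master seed; all randomness is drawn sequentially
#'   from one stream seeded once with it.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 200, module_size = 10,
                              n_modules_differential = 6,
                              effect_size = 1.0, gene_loading = 0.4,
                              noise_sd = 1.0,
                              cohorts = data.frame(
                                study = c("c1", "c2", "c3", "c4"),
                                n_poor = c(30, 20, 40, 25),
                                n_good = c(70, 50, 80, 60)),
                              batch_sd = 0.3,
                              signal_mode = c("module", "single_gene"),
                              seed = 1) {
  signal_mode <- match.arg(signal_mode)
  if (n_genes %% module_size != 0)
    stop("n_genes must be divisible by module_size")
  n_modules <- n_genes %/% module_size
  if (n_modules_differential > n_modules)
    stop("n_modules_differential exceeds the number of modules")
  if (min(effect_size, gene_loading) < 0 || noise_sd < 0 || batch_sd < 0)
    stop("effect_size, gene_loading, noise_sd and batch_sd must be >= 0")
  if (!all(c("study", "n_poor", "n_good") %in% names(cohorts)))
    stop("cohorts needs columns study, n_poor, n_good")
  if (any(cohorts$n_poor + cohorts$n_good < 1))
    stop("every cohort must have at least one patient")
  structure(list(n_genes = n_genes, module_size = module_size,
                 n_modules = n_modules,
                 n_modules_differential = n_modules_differential,
                 effect_size = effect_size, gene_loading = gene_loading,
                 noise_sd = noise_sd, cohorts = cohorts, batch_sd = batch_sd,
                 signal_mode = signal_mode, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Generate a synthetic multi-cohort study
#'
#' Draws a multi-cohort expression dataset under the model described in
#' [simulation_config()], together with its ground truth: the true gene
#' network (a clique over each module) and the set of genes belonging to
#' differential modules. Deterministic given the config's seed.
#'
#' @param config A `SimulationConfig`.
#' @return A `SyntheticStudy`: list with `dataset` (labelled
#'   `ExpressionDataset`), `true_network` (`GeneNetwork` of module cliques),
#'   `differential_genes`, and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  ng <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(ng))
  module <- rep(seq_len(config$n_modules), each = config$module_size)
  diff_modules <- seq_len(config$n_modules_differential)
  diff_genes <- gene_ids[module %in% diff_modules]

  co <- config$cohorts
  n_per <- co$n_poor + co$n_good
  n <- sum(n_per)
  patient_ids <- sprintf("p%05d", seq_len(n))
  cohort <- rep(co$study, n_per)
  outcome <- unlist(lapply(seq_len(nrow(co)), function(i)
    c(rep(1L, co$n_poor[i]), rep(0L, co$n_good[i]))))

  # latent module activities, one per (module, patient)
  Z <- matrix(stats::rnorm(config$n_modules * n), config$n_modules, n)
  shift <- ifelse(outcome == 1L, config$effect_size / 2, -config$effect_size / 2)
  if (config$signal_mode == "module" && length(diff_modules))
    Z[diff_modules, ] <- Z[diff_modules, , drop = FALSE] +
      matrix(shift, length(diff_modules), n, byrow = TRUE)

  X <- config$gene_loading * Z[module, , drop = FALSE]
  if (config$signal_mode == "single_gene" && length(diff_genes))
    X[gene_ids %in% diff_genes, ] <- X[gene_ids %in% diff_genes, , drop = FALSE] +
      matrix(shift, length(diff_genes), n, byrow = TRUE)

  if (config$batch_sd > 0) {
    B <- matrix(stats::rnorm(ng * nrow(co), sd = config$batch_sd), ng, nrow(co))
    X <- X + B[, match(cohort, co$study), drop = FALSE]
  }
  X <- X + matrix(stats::rnorm(ng * n, sd = config$noise_sd), ng, n)
  X <- X - rowMeans(X)                   # per-gene mean centering
  dimnames(X) <- list(gene_ids, patient_ids)

  edges <- do.call(rbind, lapply(seq_len(config$n_modules), function(m) {
    g <- gene_ids[module == m]
    t(utils::combn(g, 2))
  }))
  structure(list(
    dataset = expression_dataset(X, outcome = outcome, cohort = cohort,
                                 center_tol = Inf),
    true_network = gene_network(gene_ids, edges,
                                provenance = list(source = "ppi",
                                                  truth = "module cliques")),
    differential_genes = diff_genes,
    config = config), class = "SyntheticStudy")
}

#' @export
print.SyntheticStudy <- function(x, ...) {
  cat(sprintf("SyntheticStudy: %d genes x %d patients, %d cohorts, %d differential genes\n",
              length(x$dataset$gene_ids), length(x$dataset$patient_ids),
              length(unique(x$dataset$cohort)), length(x$differential_genes)))
  invisible(x)
}

#' Generate a study with the reference 12-cohort structure
#'
#' Uses the cohort sizes and class imbalance of [aces_cohort_table()]
#' (455 poor / 1,161 good / 1,616 patients over 12 studies), optionally
#' scaled down for fast runs: each cohort's class counts are multiplied by
#' `scale` and rounded (minimum 1 patient per class).
#'
#' @param scale Multiplier on every cohort's class counts (default 1).
#' @param ... Further arguments to [simulation_config()] (e.g. `n_genes`,
#'   `effect_size`, `seed`).
#' @return A `SyntheticStudy`.
#' @export
generate_multi_cohort_like_table1 <- function(scale = 1, ...) {
  tab <- aces_cohort_table()
  co <- data.frame(study = tab$study,
                   n_poor = pmax(1L, as.integer(round(tab$n_poor * scale))),
                   n_good = pmax(1L, as.integer(round(tab$n_good * scale))),
                   stringsAsFactors = FALSE)
  generate_study(simulation_config(cohorts = co, ...))
}

#' Write a synthetic study to disk
#'
#' Writes the expression TSV, phenotype TSV, true-network edge TSV, and the
#' ground-truth differential gene list.
#'
#' @param study A `SyntheticStudy`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "SyntheticStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             phenotype = file.path(dir, "phenotype.tsv"),
             network = file.path(dir, "true_network.tsv"),
             truth = file.path(dir, "differential_genes.txt"))
  write_expression(study$dataset, paths["expression"])
  write_phenotype(study$dataset, paths["phenotype"])
  write_edge_list(study$true_network, paths["network"])
  writeLines(study$differential_genes, paths["truth"])
  invisible(paths)
}
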