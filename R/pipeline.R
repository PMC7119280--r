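#' Pipeline configuration
#'
#' Single configuration object for an end-to-end run: either paths to an
#' expression TSV, phenotype TSV and PPI edge list, or a
#' `SimulationConfig` to generate the inputs. Stage parameters default to
#' the pipeline's standard settings.
#'
#' @param expression,phenotype,ppi_edges Input file paths (ignored when
#'   `simulation` is given; a simulated study supplies its own true network
#'   as the interaction network).
#' @param simulation Optional `SimulationConfig`.
#' @param coexpression_k Neighbor count for the co-expression network; when
#'   `NULL` (default) the smallest k matching the interaction network's edge
#'   count is chosen.
#' @param fdr_threshold FDR threshold for significance counts (default 0.1).
#' @param top_k_genes Genes per cohort signature for robustness
#'   (default 160).
#' @param n_folds,n_repetitions,C Cross-validation settings.
#' @param ftypes Feature types to process (default all 15).
#' @param run_evaluation,run_robustness,run_cnf Stage switches.
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(expression = NULL, phenotype = NULL,
                            ppi_edges = NULL, simulation = NULL,
                            coexpression_k = NULL, fdr_threshold = 0.1,
                            top_k_genes = 160, n_folds = 5,
                            n_repetitions = 10, C = 1.0,
                            ftypes = feature_types(),
                            run_evaluation = TRUE, run_robustness = TRUE,
                            run_cnf = TRUE, out_dir = "netfeat_out",
                            seed = 1) {
  if (is.null(simulation)) {
    for (p in c(expression, phenotype, ppi_edges))
      if (!file.exists(p)) stop("input file not found: ", p)
  } else {
    stopifnot(inherits(simulation, "SimulationConfig"))
  }
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("fdr_threshold must lie in (0, 1)")
  bad <- setdiff(ftypes, feature_types())
  if (length(bad)) stop("unknown feature type(s): ", paste(bad, collapse = ", "))
  structure(list(expression = expression, phenotype = phenotype,
                 ppi_edges = ppi_edges, simulation = simulation,
                 coexpression_k = coexpression_k,
                 fdr_threshold = fdr_threshold, top_k_genes = top_k_genes,
                 n_folds = n_folds, n_repetitions = n_repetitions, C = C,
                 ftypes = ftypes, run_evaluation = run_evaluation,
                 run_robustness = run_robustness, run_cnf = run_cnf,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order -- ingest or simulate, network
#' construction, feature computation for every requested type, significance
#' screening, cross-cohort robustness, and cross-validated evaluation
#' (including the CNF ensemble) -- writing every result table as TSV under
#' the output directory. Rerunning with an identical config reproduces
#' identical file checksums.
#'
#' @param config A `PipelineConfig`.
#' @return A run manifest: data.frame with columns `stage`, `path`, `md5`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, path) {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(stage = stage, path = path,
                 md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  stage <- function(name, expr) {
    message(sprintf("[%s] ...", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- ingest / simulate ----------------------------------------------------
  if (!is.null(config$simulation)) {
    study <- stage("simulate", generate_study(config$simulation))
    dataset <- study$dataset
    ppi <- study$true_network
    paths <- write_study(study, file.path(config$out_dir, "inputs"))
    for (p in paths) note("simulate", p)
  } else {
    dataset <- stage("ingest", {
      d <- read_expression(config$expression)
      join_phenotype(d, read_phenotype(config$phenotype))
    })
    ppi <- stage("ppi", load_edge_list(config$ppi_edges, dataset$gene_ids))
  }
  message(sprintf("  %d genes x %d patients, %d cohorts",
                  length(dataset$gene_ids), length(dataset$patient_ids),
                  length(unique(dataset$cohort))))

  # --- co-expression network ------------------------------------------------
  ce <- stage("coexpression", {
    k <- config$coexpression_k
    if (is.null(k)) {
      target <- max(1L, nrow(network_edges(ppi)))
      k <- choose_k_for_edge_count(dataset, target)$k
      message(sprintf("  chose k = %d to match %d interaction edges", k, target))
    }
    build_mutual_knn(dataset, k)
  })
  p <- file.path(config$out_dir, "coexpression_network.tsv")
  write_edge_list(ce, p); note("coexpression", p)

  net_for <- function(ft) {
    if (ft == "Gene") NULL else if (startsWith(ft, "PPI")) ppi else ce
  }

  # --- features + significance ----------------------------------------------
  sig_counts <- list()
  for (ft in config$ftypes) {
    fm <- stage(paste0("features:", ft),
                compute_features(dataset, ft, net_for(ft)))
    p <- file.path(config$out_dir, sprintf("features_%s.tsv", ft))
    write_features(fm, p); note("features", p); note("features", paste0(p, ".meta"))
    tab <- stage(paste0("significance:", ft),
                 suppressWarnings(feature_significance(fm, dataset)))
    p <- file.path(config$out_dir, sprintf("significance_%s.tsv", ft))
    write_significance(tab, p); note("significance", p)
    sig_counts[[ft]] <- data.frame(
      feature_type = ft, n_features = nrow(tab),
      n_significant = count_significant(tab, config$fdr_threshold),
      stringsAsFactors = FALSE)
  }
  p <- file.path(config$out_dir, "significant_counts.tsv")
  data.table::fwrite(do.call(rbind, sig_counts), p, sep = "\t")
  note("significance", p)

  # --- robustness -----------------------------------------------------------
  if (config$run_robustness && length(unique(dataset$cohort)) >= 2) {
    for (ft in config$ftypes) {
      res <- stage(paste0("robustness:", ft), {
        sets <- per_cohort_top_genes(dataset, ft, net_for(ft),
                                     config$top_k_genes)
        robustness_summary(sets, length(dataset$gene_ids),
                           network = if (ft == "Gene") NULL else net_for(ft))
      })
      p <- file.path(config$out_dir, sprintf("robustness_%s.tsv", ft))
      write_robustness(res, p, ft)
      note("robustness", p); note("robustness", paste0(p, ".summary"))
    }
  }

  # --- evaluation -----------------------------------------------------------
  if (config$run_evaluation) {
    summ <- list()
    for (ft in config$ftypes) {
      fm <- compute_features(dataset, ft, net_for(ft))
      res <- stage(paste0("evaluate:", ft),
                   run_cv(fm, dataset, n_folds = config$n_folds,
                          n_repetitions = config$n_repetitions,
                          seed = config$seed, C = config$C))
      p <- file.path(config$out_dir, sprintf("evaluation_%s.tsv", ft))
      write_evaluation(res, p); note("evaluation", p)
      summ[[ft]] <- data.frame(feature_type = ft, mean_auc = res$mean_auc,
                               stringsAsFactors = FALSE)
    }
    if (config$run_cnf) {
      res <- stage("evaluate:CNF",
                   run_cnf_cv(dataset, ce, ppi, n_folds = config$n_folds,
                              n_repetitions = config$n_repetitions,
                              seed = config$seed, C = config$C))
      p <- file.path(config$out_dir, "evaluation_CNF.tsv")
      write_evaluation(res, p); note("evaluation", p)
      summ[["CNF"]] <- data.frame(feature_type = "CNF", mean_auc = res$mean_auc,
                                  stringsAsFactors = FALSE)
    }
    p <- file.path(config$out_dir, "evaluation_summary.tsv")
    data.table::fwrite(do.call(rbind, summ), p, sep = "\t")
    note("evaluation", p)
  }

  manifest <- do.call(rbind, manifest)
  p <- file.path(config$out_dir, "manifest.tsv")
  data.table::fwrite(manifest, p, sep = "\t")
  manifest
}
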