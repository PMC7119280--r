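# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/.

# random labelled dataset for oracle sweeps
random_dataset <- function(n_genes, n_patients, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_patients), n_genes, n_patients,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("p%02d", seq_len(n_patients))))
  expression_dataset(x, center_tol = Inf)
}

# mutual-kNN by direct definition: sort each gene's correlation row
# (descending, ties by id), take top-k lists, intersect
oracle_mutual_knn <- function(dataset, k) {
  C <- cor(t(dataset$values))
  ids <- rownames(C)
  topk <- lapply(ids, function(g) {
    others <- setdiff(ids, g)
    others[order(-C[g, others], others)][seq_len(min(k, length(others)))]
  })
  names(topk) <- ids
  edges <- list()
  for (g in ids) for (h in topk[[g]])
    if (g < h && g %in% topk[[h]]) edges[[length(edges) + 1L]] <- c(g, h)
  if (!length(edges)) return(matrix(character(0), ncol = 2))
  e <- do.call(rbind, edges)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# node-based feature values by looping over genesets one patient at a time
oracle_node_features <- function(dataset, network, op) {
  nodes <- sort(network_nodes(network))
  nbrs <- network_neighbors(network)
  out <- matrix(NA_real_, length(nodes), length(dataset$patient_ids),
                dimnames = list(nodes, dataset$patient_ids))
  for (g in nodes) for (p in dataset$patient_ids) {
    gs <- dataset$values[c(g, nbrs[[g]]), p]
    nb <- dataset$values[nbrs[[g]], p]
    out[g, p] <- switch(op,
      MEAN = mean(gs),
      MAX = max(gs), MIN = min(gs), MED = median(gs),
      VAR = mean((gs - mean(gs))^2),
      NO = if (length(nb)) mean(nb) else dataset$values[g, p])
  }
  out
}

# BH step-up by its textbook definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))          # monotone from the largest down
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# AUC by exhaustive pairwise comparison, ties credited 0.5
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# small labelled feature matrix for CV tests
toy_feature_matrix <- function(n_features = 5, n_patients = 60, seed = 1,
                               informative = FALSE) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n_patients)
  v <- matrix(rnorm(n_features * n_patients), n_features, n_patients,
              dimnames = list(sprintf("f%02d", seq_len(n_features)),
                              sprintf("p%03d", seq_len(n_patients))))
  if (informative) v[1, ] <- v[1, ] + 2 * y
  x <- expression_dataset(v, outcome = y, center_tol = Inf)
  list(fm = compute_features(x, "Gene"), outcome = y)
}
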