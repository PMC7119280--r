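#' Construct a gene network
#'
#' An undirected simple graph over gene ids: no self-edges, each unordered
#' pair at most once, isolated (degree-0) nodes allowed. Backed by an igraph
#' object.
#'
#' @param nodes Character vector of gene ids (node set).
#' @param edges Two-column character matrix of edges (may be empty). Self
#'   edges are dropped; duplicate and reversed-duplicate pairs are collapsed.
#' @param provenance Named list describing how the network was built
#'   (e.g. `list(source = "coexpression", k = 84)`).
#' @return An object of class `GeneNetwork`.
#' @export
gene_network <- function(nodes, edges = NULL, provenance = list()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node id(s)")
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns")
    storage.mode(edges) <- "character"
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]  # self-edges
    if (nrow(edges)) {
      swap <- edges[, 1] > edges[, 2]
      edges[swap, ] <- edges[swap, 2:1]
      edges <- unique(edges)
      unknown <- setdiff(c(edges), nodes)
      if (length(unknown))
        stop("edge endpoint(s) not in node set: ",
             paste(utils::head(unknown, 5), collapse = ", "))
      edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    }
  }
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  structure(list(graph = g, provenance = provenance), class = "GeneNetwork")
}

#' @export
print.GeneNetwork <- function(x, ...) {
  cat(sprintf("GeneNetwork: %d nodes, %d edges",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  if (length(x$provenance))
    cat(sprintf(" [%s]", paste(names(x$provenance), unlist(lapply(x$provenance, toString)),
                               sep = "=", collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Network node set
#' @param network A `GeneNetwork`.
#' @return Character vector of gene ids.
#' @export
network_nodes <- function(network) igraph::V(network$graph)$name

#' Network edge list
#' @param network A `GeneNetwork`.
#' @return Two-column character matrix, each row an edge with endpoints in
#'   lexicographic order, rows sorted.
#' @export
network_edges <- function(network) {
  e <- igraph::as_edgelist(network$graph)
  if (nrow(e) == 0) return(matrix(character(0), ncol = 2))
  swap <- e[, 1] > e[, 2]
  e[swap, ] <- e[swap, 2:1]
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Node degrees
#' @param network A `GeneNetwork`.
#' @return Named integer vector of degrees over all nodes.
#' @export
network_degree <- function(network) {
  d <- igraph::degree(network$graph)
  stats::setNames(as.integer(d), igraph::V(network$graph)$name)
}

#' Neighbor lists
#' @param network A `GeneNetwork`.
#' @return Named list mapping each node to the character vector of its
#'   neighbors (empty for isolated nodes).
#' @export
network_neighbors <- function(network) {
  nodes <- network_nodes(network)
  adj <- igraph::adjacent_vertices(network$graph, v = nodes)
  stats::setNames(lapply(adj, function(v) v$name), nodes)
}

#' Load a protein-protein interaction edge list
#'
#' Reads a two-column TSV of gene-id pairs, drops self-edges, collapses
#' duplicates (including reversed duplicates), and restricts edges to pairs
#' with both endpoints in a gene universe. Every universe gene becomes a
#' node, so genes without any retained interaction are kept as isolated
#' nodes.
#'
#' @param path Path to a two-column TSV (header optional; a header row is
#'   detected when its cells are not both present in `universe`).
#' @param universe Character vector of gene ids to restrict to.
#' @return A `GeneNetwork` with provenance `source = "ppi"`. If no edge
#'   survives filtering a warning is raised and an edgeless network returned.
#' @export
load_edge_list <- function(path, universe) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!length(universe)) stop("gene universe must be nonempty")
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 2) stop("edge list must have two columns")
  e <- as.matrix(dt[, 1:2])
  # drop a header row if its cells don't look like universe genes
  if (nrow(e) && !any(e[1, ] %in% universe) && nrow(e) > 1 &&
      any(e[-1, ] %in% universe))
    e <- e[-1, , drop = FALSE]
  keep <- e[, 1] %in% universe & e[, 2] %in% universe
  e <- e[keep, , drop = FALSE]
  net <- gene_network(sort(unique(universe)), e,
                      provenance = list(source = "ppi", path = path))
  if (igraph::ecount(net$graph) == 0)
    warning("no edges remained after universe restriction and self-edge removal")
  net
}

#' Write a network edge list as TSV
#'
#' Edges are written with endpoints in lexicographic order and rows sorted,
#' so identical networks produce byte-identical files.
#'
#' @param network A `GeneNetwork`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  e <- network_edges(network)
  data.table::fwrite(data.table::data.table(gene_a = e[, 1], gene_b = e[, 2]),
                     path, sep = "\t")
  invisible(path)
}

# Rank matrix for mutual-kNN: R[i, j] = position of gene j in gene i's
# neighbor ordering (correlation descending, ties broken by gene id), with
# self excluded. Shared by build_mutual_knn and choose_k_for_edge_count.
.knn_rank_matrix <- function(dataset, ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (length(dataset$patient_ids) < 3)
    stop("need >= 3 patients to define correlations")
  x <- dataset$values
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s), correlation undefined: ",
         paste(utils::head(dataset$gene_ids[sds == 0], 5), collapse = ", "))
  C <- stats::cor(t(x))
  if (ranking == "absolute") C <- abs(C)
  n <- nrow(C)
  ids <- dataset$gene_ids
  R <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ord <- order(-C[i, ], ids)          # descending correlation, id tie-break
    ord <- ord[ord != i]                # self excluded
    R[i, ord] <- seq_len(n - 1L)
  }
  diag(R) <- n                          # self never within top-k (k <= n-1)
  R
}

#' Build a mutual k-nearest-neighbor co-expression network
#'
#' Two genes are connected iff each lies within the other's top-k most
#' co-expressed genes by Pearson correlation across all patients (all cohorts
#' pooled). "Most co-expressed" defaults to largest signed correlation;
#' ranking by absolute correlation is available as an option. Ties at the
#' k-th rank are broken deterministically by lexicographic gene id.
#'
#' @param dataset An `ExpressionDataset` (>= 3 patients; no zero-variance
#'   gene rows).
#' @param k Number of neighbors considered per gene (k >= 1).
#' @param ranking `"signed"` (default) or `"absolute"` correlation ordering.
#' @return A `GeneNetwork` with provenance `source = "coexpression"`.
#' @export
build_mutual_knn <- function(dataset, k, ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  R <- .knn_rank_matrix(dataset, ranking)
  M <- (R <= k) & (t(R) <= k)
  M[lower.tri(M, diag = TRUE)] <- FALSE
  idx <- which(M, arr.ind = TRUE)
  ids <- dataset$gene_ids
  edges <- cbind(ids[idx[, 1]], ids[idx[, 2]])
  gene_network(ids, edges,
               provenance = list(source = "coexpression", k = k,
                                 ranking = ranking))
}

#' Choose k to match a target edge count
#'
#' Returns the smallest k for which the mutual-kNN network has at least
#' `target_edges` edges (the edge count is nondecreasing in k), so the
#' co-expression network can be sized comparably to a reference network such
#' as a PPI graph.
#'
#' @param dataset An `ExpressionDataset`.
#' @param target_edges Positive integer target edge count.
#' @param ranking Correlation ordering, as in [build_mutual_knn()].
#' @return A list with `k`, `count_at_k`, and `count_at_k_minus_1`
#'   (`count_at_k_minus_1` is 0 when k = 1).
#' @export
choose_k_for_edge_count <- function(dataset, target_edges,
                                    ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  target_edges <- as.integer(target_edges)
  if (target_edges < 1) stop("target_edges must be >= 1")
  n <- length(dataset$gene_ids)
  max_edges <- n * (n - 1) / 2
  if (target_edges > max_edges)
    stop(sprintf("target_edges (%d) exceeds the complete-graph edge count (%d)",
                 target_edges, as.integer(max_edges)))
  R <- .knn_rank_matrix(dataset, ranking)
  # an edge exists at neighbor count k iff max(R[i,j], R[j,i]) <= k
  M <- pmax(R, t(R))
  vals <- sort(M[upper.tri(M)])
  k <- as.integer(vals[target_edges])   # smallest k with count(k) >= target
  list(k = k,
       count_at_k = sum(vals <= k),
       count_at_k_minus_1 = if (k > 1) sum(vals <= k - 1L) else 0L)
}

#' Degree summary over a gene subset
#'
#' Mean and median node degree, where degree counts edges incident in the
#' full network, over an optional subset of genes (all nodes by default).
#' Used to diagnose hub bias in top-ranked feature gene sets.
#'
#' @param network A `GeneNetwork`.
#' @param gene_subset Optional character vector of gene ids; must all be
#'   network nodes.
#' @return A list with `mean_degree`, `median_degree`, `n_genes`.
#' @export
degree_summary <- function(network, gene_subset = NULL) {
  d <- network_degree(network)
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, names(d))
    if (length(missing))
      stop("gene(s) not in network: ", paste(missing, collapse = ", "))
    d <- d[gene_subset]
  }
  list(mean_degree = mean(d), median_degree = stats::median(d),
       n_genes = length(d))
}

#' Mean degree implied by edge and node counts
#'
#' The handshake identity 2E/N for an undirected graph; convenient when only
#' published counts are available.
#'
#' @param n_edges Edge count.
#' @param n_nodes Node count.
#' @return 2 * n_edges / n_nodes.
#' @export
mean_degree_from_counts <- function(n_edges, n_nodes) {
  if (n_nodes <= 0) stop("n_nodes must be positive")
  2 * n_edges / n_nodes
}
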