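#' The fifteen feature type names
#'
#' `Gene` uses expression directly; the remaining types apply an operator to
#' each gene's geneset (the gene plus its direct network neighbors) or to
#' each network edge, in either a co-expression (`CE`) or protein-protein
#' interaction (`PPI`) network context.
#'
#' @return Character vector of the 15 feature type names.
#' @export
feature_types <- function() {
  c("Gene",
    paste0("CE",  c("NO", "MEAN", "MAX", "MIN", "MED", "VAR", "Edge")),
    paste0("PPI", c("NO", "MEAN", "MAX", "MIN", "MED", "VAR", "Edge")))
}

#' The eight CNF component feature types
#'
#' MEAN, MAX, MIN and MED in both network contexts; the component set of the
#' combined network features ensemble.
#'
#' @return Character vector of 8 feature type names.
#' @export
cnf_component_types <- function() {
  c(paste0("CE",  c("MEAN", "MAX", "MIN", "MED")),
    paste0("PPI", c("MEAN", "MAX", "MIN", "MED")))
}

# split "CEMEAN" -> list(context = "CE", op = "MEAN"); "Gene" -> none/Gene
.parse_ftype <- function(ftype) {
  if (!is.character(ftype) || length(ftype) != 1 || !(ftype %in% feature_types()))
    stop("unknown feature type: ", ftype,
         " (must be one of ", paste(feature_types(), collapse = ", "), ")")
  if (ftype == "Gene") return(list(context = "none", op = "Gene"))
  ctx <- if (startsWith(ftype, "PPI")) "PPI" else "CE"
  list(context = ctx, op = substring(ftype, nchar(ctx) + 1L))
}

#' Compute a feature matrix of one type
#'
#' For every patient independently, each node-based feature aggregates the
#' expression of a geneset -- a gene together with its direct neighbors in
#' the network:
#' \describe{
#'   \item{Gene}{the gene's own expression (no network).}
#'   \item{NO}{mean over the neighbors only; for an isolated gene the
#'     gene's own expression is used as the fallback.}
#'   \item{MEAN/MAX/MIN/MED}{the stated statistic over the geneset.}
#'   \item{VAR}{population variance over the geneset (denominator = geneset
#'     size, so a singleton geneset has VAR = 0 exactly).}
#'   \item{Edge}{one feature per network edge: the sum of the two endpoint
#'     genes' expression.}
#' }
#' Node-based features yield one row per network node (named by gene id);
#' edge features one row per edge (named `geneA|geneB`, endpoints sorted).
#' Rows are in sorted id order.
#'
#' @param dataset An `ExpressionDataset`.
#' @param ftype One of [feature_types()].
#' @param network A `GeneNetwork` whose nodes are a subset of the dataset's
#'   genes; required for every type except `Gene`.
#' @return A `FeatureMatrix`: a list with `values` (features x patients
#'   matrix), `feature_type`, `feature_ids`, `provenance` (per-feature set of
#'   contributing gene ids), and `network_provenance`.
#' @export
compute_features <- function(dataset, ftype, network = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  parsed <- .parse_ftype(ftype)
  X <- dataset$values

  if (parsed$op == "Gene") {
    ids <- sort(dataset$gene_ids)
    vals <- X[ids, , drop = FALSE]
    prov <- stats::setNames(as.list(ids), ids)
    return(.feature_matrix(vals, ftype, prov, list(source = "none")))
  }

  if (is.null(network) || !inherits(network, "GeneNetwork"))
    stop("feature type ", ftype, " requires a GeneNetwork")
  nodes <- network_nodes(network)
  missing <- setdiff(nodes, dataset$gene_ids)
  if (length(missing))
    stop("network gene(s) missing from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))

  if (parsed$op == "Edge") {
    e <- network_edges(network)
    if (nrow(e) == 0) {
      vals <- matrix(numeric(0), nrow = 0, ncol = ncol(X),
                     dimnames = list(NULL, colnames(X)))
      return(.feature_matrix(vals, ftype, list(), network$provenance))
    }
    vals <- X[e[, 1], , drop = FALSE] + X[e[, 2], , drop = FALSE]
    ids <- paste(e[, 1], e[, 2], sep = "|")
    rownames(vals) <- ids
    prov <- stats::setNames(lapply(seq_len(nrow(e)), function(i) e[i, ]), ids)
    return(.feature_matrix(vals, ftype, prov, network$provenance))
  }

  nodes <- sort(nodes)
  nbrs <- network_neighbors(network)[nodes]
  Xn <- X[, , drop = FALSE]

  if (parsed$op %in% c("MEAN", "NO", "VAR")) {
    # sparse-adjacency fast path: geneset sums via matrix product
    gidx <- match(nodes, dataset$gene_ids)
    deg <- lengths(nbrs)
    ii <- rep(seq_along(nodes), deg)
    jj <- match(unlist(nbrs, use.names = FALSE), dataset$gene_ids)
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                              dims = c(length(nodes), nrow(Xn)))
    nsum <- as.matrix(A %*% Xn)                 # neighbor sums
    own <- Xn[gidx, , drop = FALSE]
    vals <- switch(parsed$op,
      MEAN = (nsum + own) / (deg + 1),
      NO   = {
        v <- nsum / ifelse(deg == 0, 1, deg)
        v[deg == 0, ] <- own[deg == 0, ]        # isolated-gene fallback
        v
      },
      VAR  = {
        nsq <- as.matrix(A %*% Xn^2)
        m1 <- (nsum + own) / (deg + 1)
        m2 <- (nsq + own^2) / (deg + 1)
        pmax(m2 - m1^2, 0)                      # clamp fp negatives
      })
    rownames(vals) <- nodes
  } else {
    fun <- switch(parsed$op, MAX = max, MIN = min, MED = stats::median)
    vals <- t(vapply(nodes, function(g) {
      gs <- Xn[c(g, nbrs[[g]]), , drop = FALSE]
      apply(gs, 2, fun)
    }, numeric(ncol(Xn))))
    if (ncol(Xn) == 1) vals <- matrix(vals, ncol = 1)  # vapply drop guard
    rownames(vals) <- nodes
  }
  colnames(vals) <- colnames(Xn)
  prov <- stats::setNames(lapply(nodes, function(g) c(g, nbrs[[g]])), nodes)
  .feature_matrix(vals, ftype, prov, network$provenance)
}

.feature_matrix <- function(values, ftype, provenance, network_provenance) {
  stopifnot(all(is.finite(values)))
  structure(list(values = values,
                 feature_type = ftype,
                 feature_ids = rownames(values),
                 provenance = provenance,
                 network_provenance = network_provenance),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix [%s]: %d features x %d patients\n",
              x$feature_type, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Number of features a type yields on a network
#'
#' Node-based types yield one feature per network node; edge types one per
#' edge. `Gene` yields one per node (the network's gene universe).
#'
#' @param network A `GeneNetwork`.
#' @param ftype One of [feature_types()].
#' @return Integer count.
#' @export
feature_universe_size <- function(network, ftype) {
  parsed <- .parse_ftype(ftype)
  if (parsed$op == "Edge") nrow(network_edges(network))
  else length(network_nodes(network))
}

#' Map feature ids to their defining genes
#'
#' For node-based features the defining gene is the feature's own gene (its
#' id); for edge features the two endpoints. This is the mapping used when
#' pooling genes from ranked features, distinct from the full geneset
#' provenance used to compute feature values.
#'
#' @param feature_ids Character vector of feature ids.
#' @param ftype The feature type the ids belong to.
#' @return A list of character vectors, one per feature id.
#' @export
feature_defining_genes <- function(feature_ids, ftype) {
  parsed <- .parse_ftype(ftype)
  if (parsed$op == "Edge") strsplit(feature_ids, "|", fixed = TRUE)
  else as.list(feature_ids)
}

#' Write a feature matrix to TSV
#'
#' Same dialect as expression matrices (first column `feature_id`), with a
#' `.meta` sidecar recording the feature type and network provenance.
#'
#' @param fm A `FeatureMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  dt <- data.table::data.table(feature_id = fm$feature_ids)
  dt <- cbind(dt, data.table::as.data.table(fm$values))
  data.table::fwrite(dt, path, sep = "\t")
  meta <- c(sprintf("feature_type\t%s", fm$feature_type),
            sprintf("n_features\t%d", nrow(fm$values)),
            sprintf("network_%s\t%s", names(fm$network_provenance),
                    vapply(fm$network_provenance, toString, "")))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
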