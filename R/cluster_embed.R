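# Dimensionality reduction, mutual-kNN modularity clustering, and an exact
# stochastic-neighbor 2-D embedding used for reporting only.

#' Principal-component reduction of the signature matrix
#'
#' Top principal components of the cell x gene z-score matrix, with a
#' deterministic sign convention: the gene with the largest absolute loading
#' on each component gets a positive loading.
#'
#' @param signatures genes x cells z-score matrix.
#' @param n_pcs number of components (default 20; truncated to the rank).
#' @return cells x n_pcs matrix of scores.
#' @export
pca_reduce <- function(signatures, n_pcs = 20) {
  x <- t(signatures)
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(p$rotation))
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(signatures)
  attr(scores, "sdev") <- p$sdev
  scores
}

#' Cluster cells on a mutual-kNN graph
#'
#' Builds the mutual k-nearest-neighbor graph (Euclidean distance in PC
#' space), runs greedy multilevel modularity optimization (Louvain) at the
#' given resolution with a fixed seed, and merges singleton clusters into
#' the cluster with the nearest centroid. Cells are processed in a canonical
#' coordinate order, making the partition invariant under cell-order
#' permutation.
#'
#' @param pcs cells x d matrix (from \code{\link{pca_reduce}}).
#' @param k neighbors (default 15; must satisfy 0 < k < n_cells).
#' @param resolution modularity resolution (default 1; -> 0 gives one
#'   cluster).
#' @param seed integer seed.
#' @return factor of cluster labels ("C1", "C2", ...) named by cell, with a
#'   \code{parameters} attribute; class \code{cluster_assignment}.
#' @export
knn_cluster <- function(pcs, k = 15, resolution = 1.0, seed = 1) {
  n <- nrow(pcs)
  if (k <= 0) sc_stop("k must be positive", "scregulon_config_error")
  if (k >= n) sc_stop("k must be smaller than the number of cells",
                      "scregulon_config_error")
  ord <- do.call(order, as.data.frame(pcs))   # canonical cell order
  pcs_o <- pcs[ord, , drop = FALSE]
  d <- as.matrix(dist(pcs_o))
  # k nearest neighbors per cell (excluding self), ties broken canonically
  nn <- t(apply(d, 1, function(row) order(row)[2:(k + 1)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  mutual <- adj * Matrix::t(adj)   # edge iff both directions present
  g <- igraph::graph_from_adjacency_matrix(mutual, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- integer(n); memb[ord] <- igraph::membership(comm)
  # merge singleton (and other sub-minimum) communities into the nearest
  # larger cluster's centroid; tiny communities are mostly mutual-kNN
  # isolates and would destabilize backbone/root selection downstream
  min_size <- min(5L, max(1L, n %/% 4L))
  tab <- table(memb)
  singles <- as.integer(names(tab)[tab < min_size])
  if (length(singles) && length(tab) > length(singles)) {
    keepers <- as.integer(names(tab)[tab >= min_size])
    cents <- do.call(rbind, lapply(keepers, function(cl)
      colMeans(pcs[memb == cl, , drop = FALSE])))
    for (cl in singles) {
      i <- which(memb == cl)
      ctr <- colMeans(pcs[i, , drop = FALSE])
      dc <- colSums((t(cents) - ctr)^2)
      memb[i] <- keepers[which.min(dc)]
    }
  }
  labels <- factor(memb)
  levels(labels) <- paste0("C", seq_along(levels(labels)))
  names(labels) <- rownames(pcs)
  structure(labels,
            parameters = list(n_pcs = ncol(pcs), k = k,
                              resolution = resolution, seed = seed),
            class = c("cluster_assignment", "factor"))
}

#' 2-D stochastic neighbor embedding (reporting only)
#'
#' Exact (non-accelerated) t-SNE with a fixed seed. No downstream computation
#' consumes these coordinates.
#'
#' @param pcs cells x d matrix.
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity (clamped to the feasible maximum).
#' @return cells x 2 coordinate matrix.
#' @export
embed_2d <- function(pcs, seed = 1, perplexity = 30) {
  n <- nrow(pcs)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  set.seed(seed)
  fit <- Rtsne::Rtsne(pcs, dims = 2, theta = 0, perplexity = perplexity,
                      pca = FALSE, check_duplicates = FALSE, verbose = FALSE)
  coords <- fit$Y
  dimnames(coords) <- list(rownames(pcs), c("tsne1", "tsne2"))
  coords
}
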