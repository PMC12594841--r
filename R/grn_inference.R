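# ARACNe-style network inference: equal-frequency binned plug-in mutual
# information between candidate regulators and all genes, a permutation null
# threshold (Bonferroni across candidate edges), data-processing-inequality
# pruning of triangles, bootstrap consensus over cell resamples, and regulon
# assembly with signed modes (Spearman) and MI-derived likelihood weights.

# equal-frequency bin labels from average ranks; ties share a bin
rank_bins <- function(x, n_bins) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  pmin(n_bins, floor((r - 0.5) / n * n_bins) + 1L)
}

# Bin-count default: the plug-in MI null follows 2n MI ~ chi-square with
# (B-1)^2 degrees of freedom, so its noise floor (B-1)^2/2n only shrinks
# relative to a fixed dependence strength when B grows no faster than n^(1/3).
default_n_bins <- function(n) max(2L, min(10L, floor((n / 5)^(1/3)) + 1L))

# MI (nats) from two bin-label vectors
mi_from_bins <- function(bx, by, n_bins) {
  n <- length(bx)
  joint <- tabulate((bx - 1L) * n_bins + by, nbins = n_bins * n_bins) / n
  px <- tabulate(bx, nbins = n_bins) / n
  py <- tabulate(by, nbins = n_bins) / n
  pos <- joint > 0
  ij <- which(pos)
  i <- ((ij - 1L) %/% n_bins) + 1L
  j <- ((ij - 1L) %% n_bins) + 1L
  sum(joint[pos] * log(joint[pos] / (px[i] * py[j])))
}

#' Mutual information between two expression profiles
#'
#' Rank-transforms each vector (average ranks on ties), partitions into
#' \code{n_bins} equal-frequency bins and returns the plug-in mutual
#' information of the joint histogram, sum p_ij log(p_ij / (p_i p_j)), in
#' nats. A constant input yields MI = 0 with a warning.
#'
#' @param x,y numeric vectors of equal length >= 10.
#' @param n_bins number of bins >= 2; default floor((n/5)^(1/3)) + 1 clamped
#'   to [2, 10] (cube-root growth keeps the null's (B-1)^2/2n noise floor
#'   below fixed dependence strengths).
#' @return MI in nats (>= 0).
#' @export
mutual_information <- function(x, y, n_bins = NULL) {
  if (length(x) != length(y))
    sc_stop(sprintf("length mismatch: %d vs %d", length(x), length(y)))
  n <- length(x)
  if (n < 10) sc_stop("at least 10 observations required")
  if (is.null(n_bins)) n_bins <- default_n_bins(n)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) sc_stop("n_bins must be >= 2")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input; MI defined as 0")
    return(0)
  }
  mi_from_bins(rank_bins(x, n_bins), rank_bins(y, n_bins), n_bins)
}

#' Permutation null threshold for MI
#'
#' Computes MI on \code{n_perm} random gene pairs with one member's cells
#' permuted, and returns the empirical (1 - alpha) quantile. The default
#' alpha is Bonferroni, 0.05 / n_candidate_edges, supplied by the caller.
#'
#' @param signatures genes x cells matrix (rows are permuted/paired).
#' @param n_perm number of null draws (>= 100; default 1000).
#' @param alpha tail probability; \code{alpha = 1} returns the null minimum.
#' @param n_bins MI bin count (default from cell count).
#' @return Threshold in nats.
#' @export
mi_null_threshold <- function(signatures, n_perm = 1000, alpha = 0.05,
                              n_bins = NULL) {
  if (n_perm < 100) sc_stop("n_perm must be >= 100")
  n <- ncol(signatures)
  if (is.null(n_bins)) n_bins <- default_n_bins(n)
  g <- nrow(signatures)
  null_mi <- vapply(seq_len(n_perm), function(i) {
    pr <- sample.int(g, 2)
    mi_from_bins(rank_bins(signatures[pr[1], ], n_bins),
                 rank_bins(signatures[pr[2], sample.int(n)], n_bins),
                 as.integer(n_bins))
  }, numeric(1))
  unname(quantile(null_mi, probs = max(0, 1 - alpha), type = 1))
}

#' Construct an MI network container
#'
#' @param edges data.frame with columns \code{tf}, \code{target}, \code{mi}.
#' @param candidate_tfs regulator universe used.
#' @param n_cells number of cells the MI was computed on.
#' @return Object of class \code{mi_network}.
#' @export
mi_network <- function(edges, candidate_tfs, n_cells) {
  if (nrow(edges)) {
    if (any(edges$mi < 0)) sc_stop("MI must be non-negative")
    if (any(edges$tf == edges$target)) sc_stop("self-edges are not allowed")
    if (!all(edges$tf %in% candidate_tfs))
      sc_stop("edges must originate from candidate TFs")
  }
  structure(list(edges = edges, candidate_tfs = candidate_tfs,
                 n_cells = n_cells), class = "mi_network")
}

#' @method print mi_network
#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("mi_network: %d edge(s), %d candidate TF(s), %d cells\n",
              nrow(x$edges), length(x$candidate_tfs), x$n_cells))
  invisible(x)
}

# all TF->gene MI values above threshold, via per-TF indicator cross-products
infer_mi_edges <- function(signatures, candidate_tfs, n_bins, threshold) {
  genes <- rownames(signatures)
  tfs <- intersect(candidate_tfs, genes)
  n <- ncol(signatures)
  bins <- t(apply(signatures, 1, rank_bins, n_bins = n_bins))
  edges <- vector("list", length(tfs))
  for (k in seq_along(tfs)) {
    tf <- tfs[k]
    btf <- bins[tf, ]
    others <- setdiff(genes, tf)
    mi <- vapply(others, function(gn) mi_from_bins(btf, bins[gn, ], as.integer(n_bins)),
                 numeric(1))
    keep <- mi > threshold
    edges[[k]] <- data.frame(tf = rep(tf, sum(keep)), target = others[keep],
                             mi = unname(mi[keep]), row.names = NULL)
  }
  do.call(rbind, edges)
}

#' Apply data-processing-inequality pruning
#'
#' For every triangle (a, b, c) with all three edges present in the
#' (undirected) network, the edge (a, c) is removed when
#' MI(a,c) < min(MI(a,b), MI(b,c)) x (1 - tolerance). Removals are computed
#' against the pre-pruning network, so the result is independent of edge
#' order.
#'
#' @param net an \code{\link{mi_network}}.
#' @param tolerance in [0, 1); default 0 (strict minimum removed).
#' @return The pruned \code{mi_network}.
#' @export
apply_dpi <- function(net, tolerance = 0) {
  if (tolerance < 0 || tolerance >= 1) sc_stop("tolerance must lie in [0, 1)")
  e <- net$edges
  if (is.null(e) || nrow(e) < 3) return(net)
  # undirected MI lookup on unordered pairs
  a <- pmin(e$tf, e$target); b <- pmax(e$tf, e$target)
  key <- paste(a, b, sep = "\r")
  mi <- setNames(e$mi, key)
  # adjacency: node -> neighbors (undirected)
  nodes <- unique(c(e$tf, e$target))
  adj <- split(c(e$target, e$tf), c(e$tf, e$target))
  remove <- logical(nrow(e))
  tfs <- intersect(net$candidate_tfs, names(adj))
  # triangles require two regulator-incident edges meeting at a third node:
  # enumerate TF pairs with an edge, then their common neighbors
  tf_pairs <- e[e$tf %in% tfs & e$target %in% tfs, , drop = FALSE]
  seen <- character(0)
  for (i in seq_len(nrow(tf_pairs))) {
    t1 <- tf_pairs$tf[i]; t2 <- tf_pairs$target[i]
    pk <- paste(min(t1, t2), max(t1, t2), sep = "\r")
    if (pk %in% seen) next
    seen <- c(seen, pk)
    common <- setdiff(intersect(adj[[t1]], adj[[t2]]), c(t1, t2))
    if (!length(common)) next
    k12 <- pk
    for (g in common) {
      k1g <- paste(pmin(t1, g), pmax(t1, g), sep = "\r")
      k2g <- paste(pmin(t2, g), pmax(t2, g), sep = "\r")
      tri <- c(k12, k1g, k2g)
      vals <- mi[tri]
      if (anyNA(vals)) next
      mn <- which.min(vals)
      others_min <- min(vals[-mn])
      if (vals[mn] < others_min * (1 - tolerance)) {
        remove[key == tri[mn]] <- TRUE
      }
    }
  }
  net$edges <- e[!remove, , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

#' Infer a single MI network
#'
#' MI between each candidate regulator and every other gene, thresholded by
#' the permutation null (Bonferroni over candidate edges by default), then
#' DPI-pruned.
#'
#' @param signatures genes x cells z-score matrix.
#' @param candidate_tfs regulator universe (gene ids).
#' @param n_bins MI bins (default from cell count).
#' @param n_perm null permutations for the threshold.
#' @param alpha edge-wise significance before Bonferroni; the threshold uses
#'   alpha / n_candidate_edges.
#' @param tolerance DPI tolerance.
#' @return An \code{\link{mi_network}}.
#' @export
infer_network <- function(signatures, candidate_tfs, n_bins = NULL,
                          n_perm = 1000, alpha = 0.05, tolerance = 0) {
  n <- ncol(signatures)
  if (is.null(n_bins)) n_bins <- default_n_bins(n)
  tfs <- intersect(candidate_tfs, rownames(signatures))
  if (!length(tfs)) sc_stop("no candidate TF present in the signature rows")
  n_edges <- length(tfs) * (nrow(signatures) - 1)
  thr <- mi_null_threshold(signatures, n_perm = n_perm,
                           alpha = alpha / n_edges, n_bins = n_bins)
  edges <- infer_mi_edges(signatures, tfs, n_bins, thr)
  net <- mi_network(edges, tfs, n)
  net$threshold <- thr
  apply_dpi(net, tolerance)
}

#' Bootstrap consensus network
#'
#' Resamples cells with replacement \code{n_boot} times, infers a DPI-pruned
#' network on each resample, and keeps edges supported by at least
#' \code{support_frac} of the bootstraps; the consensus MI is the mean over
#' supporting bootstraps.
#'
#' @param signatures genes x cells z-score matrix.
#' @param candidate_tfs regulator universe.
#' @param n_boot bootstraps (>= 1; default 20).
#' @param support_frac required support in (0, 1] (default 0.5).
#' @param seed integer seed for the resamples.
#' @param ... passed to \code{\link{infer_network}}.
#' @return An \code{\link{mi_network}} with a \code{support} column on edges.
#' @export
bootstrap_consensus <- function(signatures, candidate_tfs, n_boot = 20,
                                support_frac = 0.5, seed = 1, ...) {
  if (n_boot < 1) sc_stop("n_boot must be >= 1")
  if (support_frac <= 0 || support_frac > 1)
    sc_stop("support_frac must lie in (0, 1]")
  set.seed(seed)
  n <- ncol(signatures)
  acc <- new.env(parent = emptyenv())
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    net_b <- infer_network(signatures[, idx, drop = FALSE], candidate_tfs, ...)
    e <- net_b$edges
    if (is.null(e) || !nrow(e)) next
    keys <- paste(e$tf, e$target, sep = "\r")
    for (i in seq_along(keys)) {
      prev <- acc[[keys[i]]]
      acc[[keys[i]]] <- if (is.null(prev)) c(1, e$mi[i]) else prev + c(1, e$mi[i])
    }
  }
  keys <- ls(acc)
  if (length(keys)) {
    stats_m <- vapply(keys, function(k) acc[[k]], numeric(2))
    support <- stats_m[1, ] / n_boot
    keep <- support >= support_frac
    parts <- strsplit(keys[keep], "\r", fixed = TRUE)
    edges <- data.frame(
      tf = vapply(parts, `[`, character(1), 1),
      target = vapply(parts, `[`, character(1), 2),
      mi = (stats_m[2, ] / stats_m[1, ])[keep],
      support = support[keep], row.names = NULL)
    edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(tf = character(0), target = character(0),
                        mi = numeric(0), support = numeric(0))
  }
  mi_network(edges, intersect(candidate_tfs, rownames(signatures)), n)
}

#' Assemble regulons from a pruned network
#'
#' For every TF with at least \code{min_regulon_size} surviving targets:
#' mode = Spearman correlation of the TF and target signature rows,
#' likelihood = edge MI / max edge MI within the regulon. Undersized TFs are
#' dropped with a message.
#'
#' @param net a pruned \code{\link{mi_network}}.
#' @param signatures genes x cells z-score matrix (for modes).
#' @param min_regulon_size minimum targets per emitted regulon (default 25).
#' @return A \code{\link{regulon_set}} (possibly empty, with a warning).
#' @export
assemble_regulons <- function(net, signatures, min_regulon_size = 25) {
  e <- net$edges
  if (is.null(e) || !nrow(e)) {
    warning("empty network; returning empty regulon set")
    return(regulon_set(list()))
  }
  regs <- list()
  for (tf in unique(e$tf)) {
    sub <- e[e$tf == tf, , drop = FALSE]
    sub <- sub[sub$target %in% rownames(signatures), , drop = FALSE]
    if (nrow(sub) < min_regulon_size) {
      message(sprintf("assemble_regulons: dropping %s (%d target(s) < %d)",
                      tf, nrow(sub), min_regulon_size))
      next
    }
    tf_row <- signatures[tf, ]
    mode <- vapply(sub$target, function(g) spearman(tf_row, signatures[g, ]),
                   numeric(1))
    mode[is.na(mode)] <- 0
    lik <- sub$mi / max(sub$mi)
    regs[[tf]] <- data.frame(target = sub$target, mode = unname(mode),
                             likelihood = pmin(1, pmax(lik, .Machine$double.eps)),
                             row.names = NULL)
  }
  regulon_set(regs)
}
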