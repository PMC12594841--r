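# Shared fixtures and independent oracles used across test files.

# memoized default-pipeline runs and datasets (the end-to-end and
# trajectory checks share them)
.cache <- new.env(parent = emptyenv())

cached_dataset <- function(seed = 1, ...) {
  key <- paste0("ds_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.cache[[key]]))
    .cache[[key]] <- simulate_dataset(sim_config(seed = seed, ...))
  .cache[[key]]
}

cached_pipeline <- function(seed = 1) {
  key <- paste0("pipe_", seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- suppressMessages(run_pipeline(default_run_config(seed = seed)))
  .cache[[key]]
}

# preprocessed signature matrix for a dataset
prep_signatures <- function(ds) {
  em <- normalize_log(filter_expression(as_expression_matrix(ds)))
  suppressMessages(single_cell_signatures(em))
}

# independent plug-in MI oracle: joint histogram via table(), direct formula
oracle_mi <- function(x, y, n_bins) {
  n <- length(x)
  bx <- pmin(n_bins, floor((rank(x, ties.method = "average") - 0.5) / n * n_bins) + 1)
  by <- pmin(n_bins, floor((rank(y, ties.method = "average") - 0.5) / n * n_bins) + 1)
  joint <- table(factor(bx, levels = 1:n_bins), factor(by, levels = 1:n_bins)) / n
  px <- rowSums(joint); py <- colSums(joint)
  total <- 0
  for (i in 1:n_bins) for (j in 1:n_bins)
    if (joint[i, j] > 0) total <- total + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
  as.numeric(total)
}

# brute-force DPI oracle: enumerate every triangle of the undirected network
oracle_dpi <- function(edges, tolerance = 0) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  mi <- setNames(edges$mi, key(edges$tf, edges$target))
  nodes <- unique(c(edges$tf, edges$target))
  drop <- character(0)
  if (length(nodes) >= 3) {
    cmb <- utils::combn(sort(nodes), 3)
    for (c_i in seq_len(ncol(cmb))) {
      tri <- cmb[, c_i]
      ks <- c(key(tri[1], tri[2]), key(tri[1], tri[3]), key(tri[2], tri[3]))
      vals <- mi[ks]
      if (anyNA(vals)) next
      mn <- which.min(vals)
      if (vals[mn] < min(vals[-mn]) * (1 - tolerance)) drop <- c(drop, ks[mn])
    }
  }
  keep <- !(key(edges$tf, edges$target) %in% drop)
  edges[keep, , drop = FALSE]
}

# adjusted Rand index (mclust is the oracle where available)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  exp_idx <- s(rowSums(tab)) * s(colSums(tab)) / choose(sum(tab), 2)
  (s(tab) - exp_idx) / ((s(rowSums(tab)) + s(colSums(tab))) / 2 - exp_idx)
}

# F1 of inferred vs planted target sets per TF
target_f1 <- function(regulons, truth) {
  vapply(names(truth), function(tf) {
    if (is.null(regulons[[tf]])) return(0)
    inf <- regulons[[tf]]$target; tru <- truth[[tf]]$target
    2 * length(intersect(inf, tru)) / (length(inf) + length(tru))
  }, numeric(1))
}
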