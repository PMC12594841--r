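# Filtering, log-normalization and the per-cell expression signature
# (gene-wise z-scores of log expression against the all-cells population
# reference) consumed by network inference and activity scoring.

#' Filter genes and cells
#'
#' Removes genes detected (count > 0) in fewer than \code{min_cells_per_gene}
#' cells, then cells with fewer than \code{min_genes_per_cell} detected genes
#' (gene filter first; order preserved otherwise). Idempotent for fixed
#' thresholds.
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param min_cells_per_gene,min_genes_per_cell non-negative thresholds
#'   (defaults 3 and 50).
#' @return The filtered \code{expression_matrix}.
#' @export
filter_expression <- function(em, min_cells_per_gene = 3, min_genes_per_cell = 50) {
  if (min_cells_per_gene < 0 || min_genes_per_cell < 0)
    sc_stop("filter thresholds must be non-negative")
  detected <- em$counts > 0
  keep_g <- Matrix::rowSums(detected) >= min_cells_per_gene
  counts <- em$counts[keep_g, , drop = FALSE]
  keep_c <- Matrix::colSums(counts > 0) >= min_genes_per_cell
  if (!any(keep_c))
    sc_stop("filtering removed every cell", "scregulon_empty_result")
  counts <- counts[, keep_c, drop = FALSE]
  expression_matrix(counts, em$gene_ids[keep_g], em$cell_ids[keep_c])
}

#' Log-normalize counts
#'
#' Adds a \code{lognorm} layer: log2(1 + 1e4 x count / cell_total)
#' (library-size normalization to 10^4 followed by log2(1 + x)).
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param scale_factor per-cell total after normalization (default 1e4).
#' @return The \code{expression_matrix} with \code{layers$lognorm} set.
#' @export
normalize_log <- function(em, scale_factor = 1e4) {
  totals <- Matrix::colSums(em$counts)
  if (any(totals == 0))
    sc_stop(paste0("cell(s) with zero total counts: ",
                   paste(head(em$cell_ids[totals == 0], 5), collapse = ", ")),
            "scregulon_empty_result")
  ln <- log2(1 + sweep(as.matrix(em$counts), 2, scale_factor / totals, "*"))
  em$layers$lognorm <- ln
  em
}

#' Per-cell expression signatures
#'
#' Gene-wise z-score of the log-normalized layer across all cells (population
#' reference): for every retained gene, mean over cells is 0 and sd is 1.
#' Zero-variance genes are dropped and reported via a message.
#'
#' @param em an \code{\link{expression_matrix}} with a \code{lognorm} layer,
#'   or a plain genes x cells matrix of log expression.
#' @return genes x cells matrix of z-scores (the signature matrix).
#' @export
single_cell_signatures <- function(em) {
  ln <- if (inherits(em, "expression_matrix")) {
    if (is.null(em$layers$lognorm)) sc_stop("lognorm layer missing; call normalize_log() first")
    em$layers$lognorm
  } else as.matrix(em)
  if (ncol(ln) < 2) sc_stop("at least 2 cells required (sd undefined)")
  mu <- rowMeans(ln)
  s <- apply(ln, 1, sd)
  drop <- s == 0 | !is.finite(s)
  if (any(drop))
    message(sprintf("single_cell_signatures: dropping %d zero-variance gene(s)", sum(drop)))
  z <- (ln[!drop, , drop = FALSE] - mu[!drop]) / s[!drop]
  z
}
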