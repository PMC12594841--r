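# Naiveness / cytotoxicity / exhaustion signature scoring (mean of z-scored
# member genes), Pearson correlation of scores with trajectory components,
# and LOESS trend fits.

#' Per-cell signature score
#'
#' Unweighted mean (or weighted, when \code{weights} is given) of the member
#' genes' z-score rows. Member genes are deduplicated; genes absent from the
#' signature matrix are dropped and reported via message.
#'
#' @param signatures genes x cells z-score matrix.
#' @param gene_set character vector of member gene ids.
#' @param weights optional named per-gene weights.
#' @return named numeric vector (one score per cell).
#' @export
signature_score <- function(signatures, gene_set, weights = NULL) {
  gene_set <- unique(gene_set)
  present <- gene_set %in% rownames(signatures)
  if (!any(present))
    sc_stop("no signature gene present in the expression data",
            "scregulon_missing_signature")
  if (!all(present))
    message(sprintf("signature_score: %d/%d gene(s) present (%s missing)",
                    sum(present), length(gene_set),
                    paste(gene_set[!present], collapse = ", ")))
  genes <- gene_set[present]
  m <- signatures[genes, , drop = FALSE]
  if (is.null(weights)) return(colMeans(m))
  w <- weights[genes]
  w[is.na(w)] <- 1
  colSums(m * w) / sum(w)
}

#' Phenotype score panel
#'
#' One score per cell per gene set (defaults: the shipped naiveness /
#' cytotoxicity / exhaustion signatures).
#'
#' @param signatures genes x cells z-score matrix.
#' @param gene_sets named list of gene-id vectors.
#' @return data.frame with \code{cell_id} and one column per set.
#' @export
score_panel <- function(signatures, gene_sets = default_signatures()[
                          c("naiveness", "cytotoxicity", "exhaustion")]) {
  scores <- lapply(gene_sets, function(gs)
    tryCatch(signature_score(signatures, gs),
             scregulon_missing_signature = function(e) {
               message(conditionMessage(e)); NULL
             }))
  scores <- scores[!vapply(scores, is.null, logical(1))]
  if (!length(scores)) sc_stop("no scorable gene set", "scregulon_missing_signature")
  data.frame(cell_id = colnames(signatures), scores, row.names = NULL)
}

#' Correlate phenotype scores with trajectory components
#'
#' Pearson R and two-sided p for every (component, score) pair.
#'
#' @param scores data.frame from \code{\link{score_panel}}.
#' @param components cells x 2 matrix (aligned to \code{scores} rows).
#' @return data.frame (component, score, r, p, n).
#' @export
score_component_correlation <- function(scores, components) {
  comp_names <- colnames(components)
  if (is.null(comp_names)) comp_names <- paste0("component", seq_len(ncol(components)))
  score_cols <- setdiff(names(scores), "cell_id")
  out <- list()
  for (i in seq_len(ncol(components))) {
    for (sc in score_cols) {
      ct <- cor.test(components[, i], scores[[sc]], method = "pearson")
      out[[length(out) + 1L]] <- data.frame(
        component = comp_names[i], score = sc,
        r = unname(ct$estimate), p = ct$p.value, n = nrow(scores))
    }
  }
  do.call(rbind, out)
}

#' LOESS trend fit on a grid
#'
#' Tricube-weighted local linear regression (degree 1) over the span-fraction
#' nearest neighbors, evaluated at \code{n_grid} equally spaced x points.
#'
#' @param x,y numeric vectors (n >= 10).
#' @param span neighborhood fraction in (0, 1] (default 0.5).
#' @param n_grid grid size (default 100).
#' @return data.frame (x, fitted).
#' @export
loess_fit <- function(x, y, span = 0.5, n_grid = 100) {
  if (span <= 0 || span > 1) sc_stop("span must lie in (0, 1]")
  if (length(x) < 10) sc_stop("at least 10 points required")
  if (length(unique(x)) == 1L)
    sc_stop("x is degenerate (all values equal)", "scregulon_config_error")
  fit <- loess(y ~ x, data = data.frame(x = x, y = y), span = span,
               degree = 1, family = "gaussian",
               control = loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = n_grid)
  data.frame(x = grid, fitted = as.numeric(predict(fit, newdata = data.frame(x = grid))))
}

#' @importFrom stats loess.control
NULL
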