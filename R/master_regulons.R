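# Branch-specific differential signatures (signed rank-sum z per gene),
# regulon enrichment ranking against those signatures, master-regulon
# selection and branch-GRN export, plus the expression-versus-activity
# summary contrasting the two readouts per branch and tissue.

# signed normal z from the Wilcoxon rank-sum statistic with tie correction;
# positive when `group` ranks higher than the rest
ranksum_z <- function(values, group) {
  n1 <- sum(group); n2 <- sum(!group); n <- n1 + n2
  r <- rank(values, ties.method = "average")
  w <- sum(r[group])
  mu <- n1 * (n + 1) / 2
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(0)
  (w - mu) / sqrt(sigma2)
}

#' Branch differential signature
#'
#' Per gene, a two-sided Wilcoxon rank-sum comparison of the branch's cells
#' against all other cells on log-normalized expression, reported as a signed
#' normal z (positive = higher in the branch).
#'
#' @param lognorm genes x cells log-normalized matrix (or an
#'   \code{expression_matrix} with the layer).
#' @param branch_labels factor of branch labels per cell.
#' @param branch the branch level to contrast.
#' @param min_cells minimum cells on each side (default 20).
#' @return Object of class \code{branch_signature}: list(branch, z, n_branch,
#'   n_rest); \code{z} is a named per-gene vector.
#' @export
branch_signature <- function(lognorm, branch_labels, branch, min_cells = 20) {
  if (inherits(lognorm, "expression_matrix")) {
    if (is.null(lognorm$layers$lognorm)) sc_stop("lognorm layer missing")
    lognorm <- lognorm$layers$lognorm
  }
  grp <- as.character(branch_labels) == branch
  n1 <- sum(grp); n2 <- sum(!grp)
  if (n1 < min_cells || n2 < min_cells)
    sc_stop(sprintf("branch '%s' has %d cell(s) vs %d rest; both sides need >= %d",
                    branch, n1, n2, min_cells), "scregulon_size_error")
  z <- apply(lognorm, 1, ranksum_z, group = grp)
  structure(list(branch = branch, z = z, n_branch = n1, n_rest = n2),
            class = "branch_signature")
}

#' Rank regulons against a branch signature
#'
#' Enrichment (aREA) NES of each regulon in the branch's differential z
#' signature; two-sided p from the standard normal; Benjamini-Hochberg q
#' across the branch's regulons; rows sorted by |NES| descending with
#' consecutive ranks. Regulons with insufficient overlap are skipped.
#'
#' @param branch_sig a \code{\link{branch_signature}}.
#' @param regulons a \code{\link{regulon_set}}.
#' @param min_overlap minimum overlapping targets (default 10).
#' @return Object of class \code{regulon_ranking}: data.frame (tf, nes, p, q,
#'   regulon_size, rank) with a \code{branch} attribute.
#' @export
rank_regulons <- function(branch_sig, regulons, min_overlap = 10) {
  sig <- branch_sig$z
  rows <- list()
  for (tf in names(regulons)) {
    reg <- dedupe_regulon(regulons[[tf]])
    overlap <- sum(reg$target %in% names(sig))
    if (overlap < min_overlap) {
      message(sprintf("rank_regulons: skipping %s (%d overlapping target(s))",
                      tf, overlap))
      next
    }
    a <- area_es(sig, reg, tf = tf)
    nes <- nes_from_es(a$es, a$n_eff)
    rows[[tf]] <- data.frame(tf = tf, nes = nes,
                             p = 2 * pnorm(-abs(nes)),
                             regulon_size = nrow(reg))
  }
  if (!length(rows)) sc_stop("no regulon with sufficient overlap in the signature",
                             "scregulon_overlap_error")
  df <- do.call(rbind, rows)
  df$q <- p.adjust(df$p, method = "BH")
  df <- df[order(-abs(df$nes)), c("tf", "nes", "p", "q", "regulon_size")]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, branch = branch_sig$branch, class = c("regulon_ranking", "data.frame"))
}

#' Select master regulons from a ranking
#'
#' TFs with q <= \code{q_max} and regulon size >= \code{min_size}, truncated
#' to the top \code{top_k} by |NES|; may return fewer than \code{top_k}.
#'
#' @param ranking a \code{regulon_ranking}.
#' @param q_max,min_size,top_k selection criteria (defaults 0.05, 25, 3).
#' @return character vector of TF names (possibly empty).
#' @export
select_masters <- function(ranking, q_max = 0.05, min_size = 25, top_k = 3) {
  if (!nrow(ranking)) return(character(0))
  sel <- ranking[ranking$q <= q_max & ranking$regulon_size >= min_size, , drop = FALSE]
  head(sel$tf, top_k)
}

#' Export a branch GRN edge list
#'
#' Induced TF -> target edges for the selected master regulons, with the mode
#' sign preserved from the regulon table and the target's branch z attached.
#' A target shared by two masters appears once per TF edge.
#'
#' @param masters character vector of TF names.
#' @param regulons a \code{\link{regulon_set}}.
#' @param branch_sig a \code{\link{branch_signature}}.
#' @return data.frame (tf, target, mode, likelihood, target_z).
#' @export
export_branch_grn <- function(masters, regulons, branch_sig) {
  rows <- lapply(masters, function(tf) {
    r <- regulons[[tf]]
    if (is.null(r)) sc_stop(paste0("no regulon for master '", tf, "'"))
    data.frame(tf = tf, target = r$target, mode = r$mode,
               likelihood = r$likelihood,
               target_z = unname(branch_sig$z[r$target]), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Expression versus activity summary for master regulons
#'
#' Per master TF: mean log-normalized expression and mean activity NES per
#' branch and per tissue, plus the Spearman correlation of the TF's
#' expression with the cytotoxicity score within expression-level bins
#' (low/mid/high terciles), the saturating-correlation readout.
#'
#' @param masters character vector of TF names.
#' @param em \code{expression_matrix} with a \code{lognorm} layer.
#' @param activities an \code{activity_matrix}.
#' @param branch_labels factor per cell.
#' @param tissues character/factor per cell.
#' @param cytotox_score optional numeric per cell for the binned correlation.
#' @return list(by_branch, by_tissue, expression_correlation) of data.frames.
#' @export
expression_vs_activity_report <- function(masters, em, activities,
                                          branch_labels, tissues,
                                          cytotox_score = NULL) {
  ln <- em$layers$lognorm
  if (is.null(ln)) sc_stop("lognorm layer missing")
  grp_means <- function(groups) {
    lv <- levels(factor(groups))
    do.call(rbind, lapply(masters, function(tf) {
      do.call(rbind, lapply(lv, function(g) {
        sel <- groups == g
        data.frame(tf = tf, group = g,
                   mean_expression = if (tf %in% rownames(ln))
                     mean(ln[tf, sel]) else NA_real_,
                   mean_activity = if (tf %in% rownames(activities))
                     mean(activities[tf, sel]) else NA_real_)
      }))
    }))
  }
  by_branch <- grp_means(branch_labels); names(by_branch)[2] <- "branch"
  by_tissue <- grp_means(tissues); names(by_tissue)[2] <- "tissue"
  expr_cor <- NULL
  if (!is.null(cytotox_score)) {
    expr_cor <- do.call(rbind, lapply(masters, function(tf) {
      if (!tf %in% rownames(ln)) return(NULL)
      x <- ln[tf, ]
      bins <- cut(rank(x, ties.method = "first"), breaks = 3,
                  labels = c("low", "mid", "high"))
      do.call(rbind, lapply(levels(bins), function(b) {
        sel <- bins == b
        data.frame(tf = tf, expression_bin = b,
                   spearman = spearman(x[sel], cytotox_score[sel]),
                   n = sum(sel))
      }))
    }))
  }
  list(by_branch = by_branch, by_tissue = by_tissue,
       expression_correlation = expr_cor)
}
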