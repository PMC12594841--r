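# Analytic rank-based enrichment of regulons in per-cell expression
# signatures (protein activity as NES), and self-weighted integration of
# activity matrices from multiple networks.
#
# Per gene the signature is rank-transformed to quantiles q in (0,1); the
# two-tail score is t2 = qnorm(q) (signed) and the one-tail score is
# t1 = qnorm(1/2 + |q - 1/2|) (folded: zero at mid-rank, large positive at
# both extremes). A target with mode m and weight w contributes
# w [m t2 + (1 - |m|) t1]; the enrichment score is the weighted mean and the
# NES multiplies by sqrt(n_eff), n_eff = (sum w)^2 / sum w^2, the effective
# number of independent targets (variance-1 null for a weighted mean of
# standard-normal scores).

# quantile + tail transforms for a signature vector or matrix (per column)
signature_tails <- function(sig) {
  if (is.matrix(sig)) {
    n <- nrow(sig)
    q <- apply(sig, 2, rank, ties.method = "average") / (n + 1)
  } else {
    q <- rank(sig, ties.method = "average") / (length(sig) + 1)
  }
  list(t2 = qnorm(q), t1 = qnorm(0.5 + abs(q - 0.5)))
}

# collapse duplicate targets: likelihoods add, modes combine weighted
dedupe_regulon <- function(reg) {
  if (!anyDuplicated(reg$target)) return(reg)
  sp <- split(seq_len(nrow(reg)), reg$target)
  data.frame(
    target = names(sp),
    mode = vapply(sp, function(i) sum(reg$mode[i] * reg$likelihood[i]) /
                    sum(reg$likelihood[i]), numeric(1)),
    likelihood = vapply(sp, function(i) sum(reg$likelihood[i]), numeric(1)),
    row.names = NULL)
}

#' Regulon enrichment score for one signature
#'
#' @param signature named numeric vector of per-gene z-scores (one cell or
#'   one contrast).
#' @param regulon data.frame with columns \code{target}, \code{mode},
#'   \code{likelihood} (one element of a \code{\link{regulon_set}}).
#' @param tf TF name, used in the missing-overlap error.
#' @return list(es, n_eff): the weighted-mean enrichment score and the
#'   effective target count.
#' @export
area_es <- function(signature, regulon, tf = "regulon") {
  regulon <- dedupe_regulon(regulon)
  present <- regulon$target %in% names(signature)
  if (!any(present))
    sc_stop(paste0("no regulon target of '", tf, "' overlaps the signature genes"),
            "scregulon_overlap_error")
  reg <- regulon[present, , drop = FALSE]
  tails <- signature_tails(signature)
  idx <- match(reg$target, names(signature))
  w <- reg$likelihood
  contrib <- reg$mode * tails$t2[idx] + (1 - abs(reg$mode)) * tails$t1[idx]
  es <- sum(w * contrib) / sum(w)
  list(es = es, n_eff = sum(w)^2 / sum(w^2))
}

#' Normalized enrichment score
#'
#' NES = es x sqrt(n_eff): under the gene-shuffling null of signed-mode
#' regulons the NES is approximately standard normal.
#'
#' @param es,n_eff from \code{\link{area_es}}.
#' @return NES (null units: standard deviations).
#' @export
nes_from_es <- function(es, n_eff) es * sqrt(n_eff)

#' Per-cell protein-activity matrix
#'
#' NES for every (regulon, cell). Regulons with fewer than \code{min_overlap}
#' targets present in the signature gene universe are skipped with a message.
#'
#' @param signatures genes x cells z-score matrix.
#' @param regulons a \code{\link{regulon_set}}.
#' @param min_overlap minimum overlapping targets (default 10; below this the
#'   normal null calibration of the NES degrades).
#' @param provenance network identifier recorded on the result.
#' @return regulators x cells matrix of NES with attribute
#'   \code{provenance}; class \code{activity_matrix}.
#' @export
viper_matrix <- function(signatures, regulons, min_overlap = 10,
                         provenance = "network1") {
  genes <- rownames(signatures)
  tails <- signature_tails(signatures)
  keep <- character(0)
  rows <- list()
  for (tf in names(regulons)) {
    reg <- dedupe_regulon(regulons[[tf]])
    reg <- reg[reg$target %in% genes, , drop = FALSE]
    if (nrow(reg) < min_overlap) {
      message(sprintf("viper_matrix: skipping %s (%d overlapping target(s) < %d)",
                      tf, nrow(reg), min_overlap))
      next
    }
    idx <- match(reg$target, genes)
    w <- reg$likelihood
    n_eff <- sum(w)^2 / sum(w^2)
    es <- (crossprod(w * reg$mode, tails$t2[idx, , drop = FALSE]) +
           crossprod(w * (1 - abs(reg$mode)), tails$t1[idx, , drop = FALSE])) / sum(w)
    rows[[tf]] <- as.numeric(es) * sqrt(n_eff)
    keep <- c(keep, tf)
  }
  if (!length(rows))
    sc_stop("no regulon with sufficient target overlap", "scregulon_overlap_error")
  am <- do.call(rbind, rows)
  dimnames(am) <- list(keep, colnames(signatures))
  structure(am, provenance = provenance, class = c("activity_matrix", "matrix"))
}

#' Integrate activity matrices from multiple networks
#'
#' Self-weighted integration: for regulator r and cell c with per-network
#' scores NES_k, the integrated score is
#' sum_k NES_k |NES_k| / sqrt(sum_k NES_k^2), so each network's vote is
#' weighted by its own confidence; a single network passes through unchanged,
#' and regulators present in only some networks use the available ones.
#'
#' @param activities list of \code{activity_matrix} over the same cells.
#' @return Integrated \code{activity_matrix} over the union of regulators.
#' @export
metaviper_integrate <- function(activities) {
  if (!length(activities)) sc_stop("at least one activity matrix required")
  if (length(activities) == 1L) return(activities[[1]])
  cells <- Reduce(intersect, lapply(activities, colnames))
  if (!length(cells))
    sc_stop("activity matrices share no cells", "scregulon_alignment_error")
  regs <- Reduce(union, lapply(activities, rownames))
  num <- matrix(0, length(regs), length(cells), dimnames = list(regs, cells))
  den <- matrix(0, length(regs), length(cells), dimnames = list(regs, cells))
  for (am in activities) {
    r <- intersect(rownames(am), regs)
    m <- am[r, cells, drop = FALSE]
    num[r, ] <- num[r, ] + m * abs(m)
    den[r, ] <- den[r, ] + m^2
  }
  out <- num / sqrt(pmax(den, .Machine$double.xmin))
  out[den == 0] <- 0
  prov <- unlist(lapply(activities, function(a) attr(a, "provenance")))
  structure(out, provenance = prov, class = c("activity_matrix", "matrix"))
}
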