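# Observed/expected tissue-preference statistic per cluster x tissue
# (R_O/E, the ratio of observed cell numbers to the chi-square independence
# expectation, adjusting for cell-sampling biases), enrichment calls, and a
# per-patient one-way ANOVA of tissue effects.

#' Observed/expected tissue-preference table
#'
#' expected[c, t] = row_total_c x col_total_t / grand_total (the chi-square
#' independence expectation); R_O/E = observed / expected. Cells with zero
#' expectation are reported as NA (undefined), never infinite.
#'
#' @param observed cluster x tissue matrix of non-negative integer counts.
#' @return Object of class \code{roe_table}: list with \code{roe},
#'   \code{observed}, \code{expected}, \code{chisq_contrib}.
#' @export
roe <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || any(observed != round(observed)))
    sc_stop("observed must contain non-negative integers")
  total <- sum(observed)
  if (total == 0) sc_stop("all-zero contingency table", "scregulon_empty_result")
  expected <- outer(rowSums(observed), colSums(observed)) / total
  r <- observed / expected
  r[expected == 0] <- NA_real_
  chisq <- (observed - expected)^2 / expected
  chisq[expected == 0] <- NA_real_
  structure(list(roe = r, observed = observed, expected = expected,
                 chisq_contrib = chisq), class = "roe_table")
}

#' @method print roe_table
#' @export
print.roe_table <- function(x, ...) {
  cat("R_O/E (observed / chi-square expectation):\n")
  print(round(x$roe, 3))
  invisible(x)
}

#' Enrichment call from an R_O/E value
#'
#' R_O/E > 1 is enrichment, < 1 depletion, = 1 (to 1e-12) neutral. Values at
#' or above \code{strong} (default 2.5, the conventional cutoff for a
#' cluster "primarily localized" in one compartment) are additionally flagged
#' in the \code{strong} attribute.
#'
#' @param roe_value numeric vector of R_O/E values (NA allowed).
#' @return character vector in {enriched, depleted, neutral} with a logical
#'   \code{strong} attribute.
#' @export
enrichment_call <- function(roe_value, strong = 2.5) {
  call <- ifelse(is.na(roe_value), NA_character_,
                 ifelse(abs(roe_value - 1) <= 1e-12, "neutral",
                        ifelse(roe_value > 1, "enriched", "depleted")))
  structure(call, strong = !is.na(roe_value) & roe_value >= strong)
}

#' Summarize tissue preference per cluster x tissue
#'
#' @param clusters factor of cluster labels per cell.
#' @param annotation data.frame with \code{tissue} (and \code{patient} for
#'   \code{\link{per_patient_anova}}) aligned to the cells.
#' @return data.frame (cluster, tissue, observed, expected, roe, call,
#'   strong).
#' @export
tissue_preference_table <- function(clusters, annotation) {
  obs <- table(cluster = clusters, tissue = annotation$tissue)
  rt <- roe(unclass(obs))
  df <- as.data.frame.table(rt$roe, responseName = "roe")
  names(df)[1:2] <- c("cluster", "tissue")
  df$observed <- as.vector(rt$observed)
  df$expected <- as.vector(rt$expected)
  cl <- enrichment_call(df$roe)
  df$call <- as.character(cl)
  df$strong <- attr(cl, "strong")
  df[order(df$cluster, df$tissue), c("cluster", "tissue", "observed",
                                     "expected", "roe", "call", "strong")]
}

#' Per-patient one-way ANOVA of tissue preference
#'
#' For each cluster, computes that cluster's R_O/E within every patient's own
#' cluster x tissue contingency table, then one-way ANOVA of these per-patient
#' replicates across tissues. Patients contributing no cells to a tissue are
#' excluded (logged via message); clusters without at least two tissues
#' having two patient replicates each get an undefined (NA) p, never 1.
#'
#' @param clusters factor of cluster labels per cell.
#' @param annotation data.frame with \code{tissue} and \code{patient}.
#' @return data.frame (cluster, F, p, n_replicates) plus the per-patient
#'   replicate table in attribute \code{replicates}.
#' @export
per_patient_anova <- function(clusters, annotation) {
  patients <- unique(annotation$patient)
  reps <- list()
  for (p in patients) {
    sel <- annotation$patient == p
    tab <- table(cluster = clusters[sel],
                 tissue = factor(annotation$tissue[sel],
                                 levels = sort(unique(annotation$tissue))))
    if (sum(tab) == 0) next
    empty_tissues <- colnames(tab)[colSums(tab) == 0]
    if (length(empty_tissues))
      message(sprintf("per_patient_anova: patient %s has no cells in %s; excluded there",
                      p, paste(empty_tissues, collapse = ", ")))
    rt <- roe(unclass(tab))
    df <- as.data.frame.table(rt$roe, responseName = "roe")
    names(df)[1:2] <- c("cluster", "tissue")
    df$patient <- p
    reps[[p]] <- df[!is.na(df$roe), , drop = FALSE]
  }
  reps <- do.call(rbind, reps)
  out <- lapply(levels(factor(clusters)), function(cl) {
    d <- reps[reps$cluster == cl, , drop = FALSE]
    enough <- length(unique(d$tissue)) >= 2 &&
      sum(table(d$tissue) >= 2) >= 2 && nrow(d) > length(unique(d$tissue))
    if (!enough)
      return(data.frame(cluster = cl, F = NA_real_, p = NA_real_,
                        n_replicates = nrow(d)))
    gm <- tapply(d$roe, d$tissue, mean)
    if (var(gm[!is.na(gm)]) == 0)   # no between-tissue variation at all
      return(data.frame(cluster = cl, F = 0, p = 1, n_replicates = nrow(d)))
    fit <- summary(aov(roe ~ tissue, data = d))[[1]]
    data.frame(cluster = cl, F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
               n_replicates = nrow(d))
  })
  res <- do.call(rbind, out)
  attr(res, "replicates") <- reps
  res
}
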