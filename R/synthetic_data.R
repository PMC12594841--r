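# Synthetic scRNA-seq generator with planted ground truth.
#
# Emulates the study design the pipeline targets: CD8+ cells from several
# patients across three tissue compartments (blood / normal / tumor), a
# five-segment developmental topology (naive root -> memory trunk ->
# cytotoxic-effector / exhausted / dysfunctional branches), transcription
# factors whose latent activity ramps up inside one driven segment, signed
# regulons wiring that activity into negative-binomial counts, and phenotype
# marker genes so that signature scoring and root selection are testable.

SEGMENTS <- c("root", "trunk", "effector", "exhausted", "dysfunctional")

# pseudotime support per segment; root cells rest at exactly 0
SEGMENT_INTERVALS <- list(
  root          = c(0, 0),
  trunk         = c(0.2, 0.5),
  effector      = c(0.5, 1.0),
  exhausted     = c(0.5, 1.0),
  dysfunctional = c(0.5, 1.0)
)

MARKER_GENES <- list(
  naiveness    = c("LEF1", "TCF7", "SELL", "CCR7"),
  cytotoxicity = c("GNLY", "GZMB", "PRF1"),
  exhaustion   = c("HAVCR2", "TIGIT", "PDCD1")
)

#' Simulation configuration
#'
#' Defines one synthetic dataset: its size, planted regulon structure, the
#' five-segment branch topology, per-segment tissue sampling probabilities and
#' the observation model. Defaults are the package's reference study
#' conditions: 600 cells x 300 genes, 6 TFs with 40 signed targets each at
#' effect strength 1.5, negative-binomial counts with size 2 around a deep
#' (10^4 counts/cell) library, and tissue skews that place the naive root in
#' circulation and the exhausted/dysfunctional branches in tumor.
#'
#' @param n_genes,n_tfs,regulon_size,n_cells,n_patients,n_tissues sizes.
#' @param frac_repressed fraction of targets with negative mode.
#' @param branch_spec named numeric vector of cell fractions over the five
#'   segments (root, trunk, effector, exhausted, dysfunctional); must sum to 1.
#' @param tissue_probs segment x tissue matrix of sampling probabilities; each
#'   row must sum to 1.
#' @param effect_strength log-scale regulon effect of a fully active TF.
#' @param marker_strength log-scale effect on phenotype marker genes.
#' @param nb_dispersion negative-binomial size parameter (variance
#'   mu + mu^2/size; Poisson in the limit size -> Inf).
#' @param library_size_mean mean cell library size (counts).
#' @param library_size_sdlog log-sd of the lognormal cell size factors.
#' @param tf_self_expression should a TF's own transcript track its activity?
#'   Turning this off emulates regulators whose activity is invisible in their
#'   own expression.
#' @param target_overlap fraction of each regulon's targets shared with the
#'   previous TF's regulon (stress-test flag; default 0 = disjoint).
#' @param seed integer seed.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 300L, n_tfs = 6L, regulon_size = 40L,
                       frac_repressed = 0.3, n_cells = 600L, n_patients = 5L,
                       n_tissues = 3L,
                       branch_spec = c(root = 0.20, trunk = 0.25, effector = 0.25,
                                       exhausted = 0.15, dysfunctional = 0.15),
                       tissue_probs = NULL,
                       effect_strength = 1.5, marker_strength = 2.0,
                       nb_dispersion = 2, library_size_mean = 1e4,
                       library_size_sdlog = 0.25,
                       tf_self_expression = TRUE, target_overlap = 0,
                       seed = 1L) {
  tissues <- c("blood", "normal", "tumor")[seq_len(n_tissues)]
  if (n_tissues > 3) tissues <- c(tissues, paste0("tissue", 4:n_tissues))
  if (is.null(tissue_probs)) {
    tissue_probs <- rbind(
      root          = c(0.70, 0.20, 0.10),
      trunk         = c(0.30, 0.40, 0.30),
      effector      = c(0.45, 0.45, 0.10),
      exhausted     = c(0.10, 0.20, 0.70),
      dysfunctional = c(0.10, 0.20, 0.70)
    )[, seq_len(n_tissues), drop = FALSE]
    tissue_probs <- tissue_probs / rowSums(tissue_probs)
  }
  colnames(tissue_probs) <- tissues
  cfg <- structure(list(
    n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
    regulon_size = as.integer(regulon_size), frac_repressed = frac_repressed,
    n_cells = as.integer(n_cells), n_patients = as.integer(n_patients),
    n_tissues = as.integer(n_tissues), tissues = tissues,
    branch_spec = branch_spec, tissue_probs = tissue_probs,
    effect_strength = effect_strength, marker_strength = marker_strength,
    nb_dispersion = nb_dispersion, library_size_mean = library_size_mean,
    library_size_sdlog = library_size_sdlog,
    tf_self_expression = tf_self_expression, target_overlap = target_overlap,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1 || cfg$n_tfs < 1 || cfg$regulon_size < 1)
    sc_stop("n_genes, n_tfs and regulon_size must be positive", "scregulon_config_error")
  if (cfg$frac_repressed < 0 || cfg$frac_repressed > 1)
    sc_stop("frac_repressed must lie in [0, 1]", "scregulon_config_error")
  if (!setequal(names(cfg$branch_spec), SEGMENTS))
    sc_stop(paste0("branch_spec must name segments: ", paste(SEGMENTS, collapse = ", ")),
            "scregulon_config_error")
  if (abs(sum(cfg$branch_spec) - 1) > 1e-9)
    sc_stop(sprintf("branch_spec fractions sum to %.12f, not 1", sum(cfg$branch_spec)),
            "scregulon_config_error")
  if (any(cfg$branch_spec < 0))
    sc_stop("branch_spec fractions must be non-negative", "scregulon_config_error")
  if (!all(rownames(cfg$tissue_probs) %in% SEGMENTS))
    sc_stop("tissue_probs rows must be named by segment", "scregulon_config_error")
  bad <- which(abs(rowSums(cfg$tissue_probs) - 1) > 1e-9)
  if (length(bad))
    sc_stop(paste0("tissue_probs row(s) not summing to 1: ",
                   paste(rownames(cfg$tissue_probs)[bad], collapse = ", ")),
            "scregulon_config_error")
  if (any(cfg$tissue_probs < 0))
    sc_stop("tissue_probs must be non-negative", "scregulon_config_error")
  n_marker <- length(unlist(MARKER_GENES))
  # LEF1/TCF7 double as candidate TFs; reserve space conservatively
  if (cfg$n_tfs * cfg$regulon_size * (1 - cfg$target_overlap) >
      cfg$n_genes - cfg$n_tfs - n_marker)
    sc_stop("regulon_size x n_tfs exceeds available non-TF genes", "scregulon_config_error")
  if (cfg$nb_dispersion <= 0)
    sc_stop("nb_dispersion must be positive", "scregulon_config_error")
  invisible(cfg)
}

# TF symbols used for planted regulators, ordered so that the round-robin
# segment assignment (effector first) lands each on its canonical program
planted_tf_symbols <- function(n_tfs) {
  base <- c("ZEB2", "TOX", "NR4A1", "EOMES", "LEF1", "TBX21", "PRDM1",
            "BACH2", "ID2", "RUNX3", "KLF2", "FOXO1")
  if (n_tfs <= length(base)) base[seq_len(n_tfs)]
  else c(base, sprintf("TF%03d", seq_len(n_tfs - length(base))))
}

# segments in driven-assignment order: the effector branch is always covered
driven_order <- c("effector", "exhausted", "dysfunctional", "trunk", "root")

#' Generate the developmental topology, tissues and patients
#'
#' Assigns each cell a segment (multinomially by the configured fractions), a
#' pseudotime (0 for root cells; uniform within the segment's interval along
#' the tree path otherwise), a tissue (from the segment's tissue probability
#' row) and a patient (uniform).
#'
#' @param config a \code{\link{sim_config}}.
#' @return Object of class \code{ground_truth} with fields \code{segment},
#'   \code{pseudotime}, \code{tissue}, \code{patient}, \code{cell_ids}.
#' @export
generate_topology <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_cells
  frac <- config$branch_spec[SEGMENTS]
  segment <- factor(sample(SEGMENTS, n, replace = TRUE, prob = frac),
                    levels = SEGMENTS)
  pt <- numeric(n)
  for (s in SEGMENTS) {
    idx <- which(segment == s)
    iv <- SEGMENT_INTERVALS[[s]]
    pt[idx] <- if (iv[1] == iv[2]) iv[1] else runif(length(idx), iv[1], iv[2])
  }
  tissue <- character(n)
  for (s in SEGMENTS) {
    idx <- which(segment == s)
    if (!length(idx)) next
    tissue[idx] <- sample(config$tissues, length(idx), replace = TRUE,
                          prob = config$tissue_probs[s, ])
  }
  patient <- sample(sprintf("P%02d", seq_len(config$n_patients)), n, replace = TRUE)
  structure(list(
    cell_ids = sprintf("cell%04d", seq_len(max(n, 0L))),
    segment = segment, pseudotime = pt,
    tissue = factor(tissue, levels = config$tissues),
    patient = factor(patient)), class = "ground_truth")
}

# smooth ramp of pseudotime within a segment's interval, in [0, 1]
segment_ramp <- function(pt, segment, seg) {
  iv <- SEGMENT_INTERVALS[[seg]]
  r <- numeric(length(pt))
  idx <- which(segment == seg)
  r[idx] <- if (iv[1] == iv[2]) 1 else (pt[idx] - iv[1]) / (iv[2] - iv[1])
  r
}

#' Plant latent transcription-factor activities
#'
#' Each TF drives exactly one segment (round-robin over effector, exhausted,
#' dysfunctional, trunk, root, so the effector branch is always covered);
#' inside the driven segment its activity is \code{effect_strength} times a
#' smooth pseudotime ramp, ~0 elsewhere, plus Gaussian noise with
#' sd = 0.1 x effect_strength. When a segment receives more than one TF the
#' second runs an early program (declining ramp, 1 - ramp) so that two
#' regulators of one branch remain statistically distinguishable, as early
#' and late effector programs are in real differentiation.
#'
#' @param truth a \code{ground_truth} from \code{\link{generate_topology}}.
#' @param config the \code{\link{sim_config}}.
#' @return The \code{ground_truth} with \code{tf_activity} (TF x cell matrix)
#'   and \code{driven_segment} filled in.
#' @export
simulate_tf_activity <- function(truth, config) {
  if (is.null(truth$segment)) sc_stop("topology must be generated first")
  set.seed(config$seed + 1L)
  tfs <- planted_tf_symbols(config$n_tfs)
  driven <- driven_order[((seq_len(config$n_tfs) - 1L) %% length(driven_order)) + 1L]
  names(driven) <- tfs
  n <- length(truth$cell_ids)
  act <- matrix(0, nrow = config$n_tfs, ncol = n, dimnames = list(tfs, truth$cell_ids))
  round_idx <- (seq_len(config$n_tfs) - 1L) %/% length(driven_order)
  for (i in seq_len(config$n_tfs)) {
    ramp <- segment_ramp(truth$pseudotime, truth$segment, driven[i])
    in_seg <- truth$segment == driven[i]
    if (round_idx[i] %% 2L == 1L) ramp[in_seg] <- 1 - ramp[in_seg]
    act[i, ] <- config$effect_strength * ramp +
      rnorm(n, 0, 0.1 * config$effect_strength)
  }
  truth$tf_activity <- act
  truth$driven_segment <- driven
  truth
}

# gene universe: TFs first, then phenotype markers, then numbered filler
build_gene_ids <- function(config) {
  tfs <- planted_tf_symbols(config$n_tfs)
  markers <- setdiff(unlist(MARKER_GENES, use.names = FALSE), tfs)
  n_fill <- config$n_genes - length(tfs) - length(markers)
  if (n_fill < 0) sc_stop("n_genes too small for TFs + marker genes", "scregulon_config_error")
  c(tfs, markers, sprintf("G%04d", seq_len(n_fill)))
}

# assign signed targets per TF from the filler pool
plant_regulons <- function(config, gene_ids) {
  tfs <- planted_tf_symbols(config$n_tfs)
  pool <- setdiff(gene_ids, c(tfs, unlist(MARKER_GENES, use.names = FALSE)))
  n_new <- round(config$regulon_size * (1 - config$target_overlap))
  regs <- list()
  prev_targets <- character(0)
  used <- character(0)
  for (i in seq_along(tfs)) {
    n_shared <- config$regulon_size - n_new
    shared <- if (n_shared > 0 && length(prev_targets))
      sample(prev_targets, min(n_shared, length(prev_targets))) else character(0)
    fresh <- sample(setdiff(pool, used), config$regulon_size - length(shared))
    targets <- c(shared, fresh)
    used <- union(used, fresh)
    n_rep <- round(config$frac_repressed * length(targets))
    mode <- rep(1, length(targets))
    if (n_rep > 0) mode[sample(length(targets), n_rep)] <- -1
    regs[[tfs[i]]] <- data.frame(target = targets, mode = mode, likelihood = 1,
                                 row.names = NULL)
    prev_targets <- targets
  }
  regulon_set(regs)
}

#' Draw negative-binomial counts from the planted model
#'
#' For gene g and cell c the log-mean is
#' baseline_g + sum over TFs of mode(tf, g) x activity(tf, c) for g in the
#' TF's regulon, plus marker-program effects for the phenotype marker genes;
#' counts are NegativeBinomial(mean = s_c exp(mu_gc), size = nb_dispersion)
#' with lognormal cell size factors s_c. TF transcripts track their own
#' activity when \code{tf_self_expression} is on.
#'
#' @param truth \code{ground_truth} with activities filled.
#' @param config the \code{\link{sim_config}}.
#' @return Object of class \code{synthetic_dataset}: an
#'   \code{\link{expression_matrix}}-compatible counts slot plus annotation
#'   and the \code{truth}.
#' @export
simulate_counts <- function(truth, config) {
  if (is.null(truth$tf_activity)) sc_stop("tf activities must be simulated first")
  if (config$nb_dispersion <= 0)
    sc_stop("nb_dispersion must be positive", "scregulon_config_error")
  set.seed(config$seed + 2L)
  gene_ids <- build_gene_ids(config)
  regs <- plant_regulons(config, gene_ids)
  n <- length(truth$cell_ids); g <- length(gene_ids)

  if (n == 0L) {
    counts <- matrix(integer(0), nrow = g, ncol = 0,
                     dimnames = list(gene_ids, character(0)))
    truth$regulons <- regs
    return(structure(list(
      counts = counts, gene_ids = gene_ids, cell_ids = character(0),
      annotation = data.frame(cell_id = character(0), tissue = character(0),
                              patient = character(0), segment = character(0)),
      truth = truth), class = "synthetic_dataset"))
  }

  # baseline relative abundance: skewed, as in real transcriptomes
  base <- rgamma(g, shape = 1.2, rate = 1)
  base <- pmax(base, 1e-3)
  baseline <- log(base / sum(base))
  mu_log <- matrix(baseline, nrow = g, ncol = n, dimnames = list(gene_ids, truth$cell_ids))

  tfs <- rownames(truth$tf_activity)
  for (tf in tfs) {
    r <- regs[[tf]]
    idx <- match(r$target, gene_ids)
    mu_log[idx, ] <- mu_log[idx, ] + outer(r$mode, truth$tf_activity[tf, ])
    if (isTRUE(config$tf_self_expression))
      mu_log[tf, ] <- mu_log[tf, ] + truth$tf_activity[tf, ]
  }

  # phenotype marker programs (deterministic functions of the topology)
  naive_ramp <- 1 - truth$pseudotime
  eff_ramp <- segment_ramp(truth$pseudotime, truth$segment, "effector")
  exh_ramp <- segment_ramp(truth$pseudotime, truth$segment, "exhausted") +
    0.6 * segment_ramp(truth$pseudotime, truth$segment, "dysfunctional")
  ms <- config$marker_strength
  for (gn in setdiff(MARKER_GENES$naiveness, tfs))
    mu_log[gn, ] <- mu_log[gn, ] + ms * naive_ramp
  for (gn in setdiff(MARKER_GENES$cytotoxicity, tfs))
    mu_log[gn, ] <- mu_log[gn, ] + ms * eff_ramp
  for (gn in setdiff(MARKER_GENES$exhaustion, tfs))
    mu_log[gn, ] <- mu_log[gn, ] + ms * exh_ramp

  size_factors <- rlnorm(n, meanlog = log(config$library_size_mean),
                         sdlog = config$library_size_sdlog)
  # renormalize per cell so s_c is the expected library size
  rel <- exp(mu_log)
  rel <- sweep(rel, 2, colSums(rel), "/")
  mean_mat <- sweep(rel, 2, size_factors, "*")

  counts <- matrix(rnbinom(g * n, size = config$nb_dispersion, mu = as.vector(mean_mat)),
                   nrow = g, ncol = n, dimnames = list(gene_ids, truth$cell_ids))
  truth$regulons <- regs
  structure(list(
    counts = counts, gene_ids = gene_ids, cell_ids = truth$cell_ids,
    annotation = data.frame(cell_id = truth$cell_ids,
                            tissue = as.character(truth$tissue),
                            patient = as.character(truth$patient),
                            segment = as.character(truth$segment),
                            row.names = NULL),
    truth = truth), class = "synthetic_dataset")
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: topology, TF activities, counts.
#'
#' @param config a \code{\link{sim_config}} (default: reference conditions).
#' @return A \code{synthetic_dataset}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- generate_topology(config)
  truth <- simulate_tf_activity(truth, config)
  simulate_counts(truth, config)
}

#' @method print synthetic_dataset
#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genes x %d cells; %d planted regulon(s)\n",
              length(x$gene_ids), length(x$cell_ids), length(x$truth$regulons)))
  invisible(x)
}

#' Convert a synthetic dataset to an expression matrix
#' @param ds a \code{synthetic_dataset}.
#' @return An \code{\link{expression_matrix}}.
#' @export
as_expression_matrix <- function(ds) {
  expression_matrix(ds$counts, ds$gene_ids, ds$cell_ids)
}

#' Write a synthetic dataset to disk
#'
#' Emits the Matrix Market counts triplet, \code{annotation.tsv} and the
#' ground-truth files \code{regulons.tsv}, \code{activity.tsv} and
#' \code{pseudotime.tsv}. Round-trips losslessly through
#' \code{\link{read_counts}} / \code{\link{read_annotation}} /
#' \code{\link{read_regulon_table}}.
#'
#' @param ds a \code{synthetic_dataset}.
#' @param dir output directory.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(as_expression_matrix(ds), dir)
  write.table(ds$annotation, file.path(dir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_regulon_table(ds$truth$regulons, file.path(dir, "regulons.tsv"))
  act <- data.frame(tf = rownames(ds$truth$tf_activity),
                    ds$truth$tf_activity, check.names = FALSE)
  write.table(act, file.path(dir, "activity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pt <- data.frame(cell_id = ds$cell_ids,
                   pseudotime = ds$truth$pseudotime,
                   segment = as.character(ds$truth$segment))
  write.table(pt, file.path(dir, "pseudotime.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
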