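# One reproducible run: configuration validation, staged execution
# (simulate -> preprocess -> cluster -> score -> trajectory -> tissue ->
# branch GRNs -> activity -> rank), plain-text TSV outputs and a manifest
# with per-file hashes. A single global seed is fanned out per stage by
# fixed offsets.

KNOWN_CONFIG_KEYS <- list(
  top = c("seed", "input", "simulate", "preprocess", "cluster", "grn",
          "activity", "rank", "score"),
  input = c("counts_dir", "counts_tsv", "annotation"),
  simulate = c("n_genes", "n_tfs", "regulon_size", "frac_repressed", "n_cells",
               "n_patients", "n_tissues", "effect_strength", "marker_strength",
               "nb_dispersion", "library_size_mean", "library_size_sdlog",
               "tf_self_expression", "target_overlap"),
  preprocess = c("min_cells_per_gene", "min_genes_per_cell"),
  cluster = c("n_pcs", "k", "resolution", "embed"),
  grn = c("n_bins", "n_boot", "support_frac", "min_regulon_size", "tolerance",
          "n_perm", "min_branch_cells", "candidate_tfs"),
  activity = c("min_overlap"),
  rank = c("q_max", "min_size", "top_k"),
  score = c("gmt")
)

#' Default run configuration
#'
#' The reference conditions: simulate the default synthetic dataset and run
#' every stage with the documented module defaults.
#'
#' @param seed global seed.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1) {
  list(seed = seed,
       simulate = list(),
       preprocess = list(min_cells_per_gene = 3, min_genes_per_cell = 50),
       cluster = list(n_pcs = 20, k = 15, resolution = 1.0, embed = FALSE),
       grn = list(n_boot = 20, support_frac = 0.5, min_regulon_size = 25,
                  tolerance = 0.0, n_perm = 1000, min_branch_cells = 200),
       activity = list(min_overlap = 10),
       rank = list(q_max = 0.05, min_size = 25, top_k = 3))
}

#' Validate a run configuration
#'
#' Rejects unknown top-level or per-stage keys, naming the offending key.
#'
#' @param config nested list.
#' @return The config, invisibly.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), KNOWN_CONFIG_KEYS$top)
  if (length(unknown))
    sc_stop(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
            "scregulon_config_error")
  for (stage in intersect(names(config), setdiff(KNOWN_CONFIG_KEYS$top, "seed"))) {
    unknown <- setdiff(names(config[[stage]]), KNOWN_CONFIG_KEYS[[stage]])
    if (length(unknown))
      sc_stop(paste0("unknown config key(s) under '", stage, "': ",
                     paste(unknown, collapse = ", ")),
              "scregulon_config_error")
  }
  if (is.null(config$seed)) sc_stop("config needs a seed", "scregulon_config_error")
  if (is.null(config$simulate) && is.null(config$input))
    sc_stop("config needs either a simulate block or an input block",
            "scregulon_config_error")
  invisible(config)
}

cfg_get <- function(config, stage, key, default) {
  v <- config[[stage]][[key]]
  if (is.null(v)) default else v
}

#' Run the full pipeline
#'
#' Executes all stages on either a simulated dataset (config block
#' \code{simulate}) or on-disk inputs (config block \code{input}), optionally
#' writing every table plus a manifest (config, per-file md5 hashes, seed)
#' under \code{out_dir}. Identical config + seed give identical outputs.
#'
#' @param config nested list (see \code{\link{default_run_config}} /
#'   \code{\link{read_run_config}}).
#' @param out_dir optional output directory.
#' @return Object of class \code{pipeline_result}: list with the dataset,
#'   expression matrix, signatures, clusters, scores, trajectory, tissue
#'   tables, branch networks/regulons, activities, rankings, masters and
#'   reports.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  validate_run_config(config)
  seed <- config$seed

  # --- data ---
  ds <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- stage_seed(seed, "simulate")
    ds <- simulate_dataset(do.call(sim_config, sim_args))
    em <- as_expression_matrix(ds)
    annotation <- ds$annotation
  } else {
    if (!is.null(config$input$counts_dir)) {
      em <- read_counts(config$input$counts_dir, "mtx")
    } else {
      em <- read_counts(config$input$counts_tsv, "tsv")
    }
    annotation <- read_annotation(config$input$annotation, em$cell_ids)
  }

  # --- preprocess ---
  em <- filter_expression(em,
          cfg_get(config, "preprocess", "min_cells_per_gene", 3),
          cfg_get(config, "preprocess", "min_genes_per_cell", 50))
  annotation <- annotation[match(em$cell_ids, annotation$cell_id), , drop = FALSE]
  em <- normalize_log(em)
  sig <- single_cell_signatures(em)

  # --- cluster ---
  pcs <- pca_reduce(sig, cfg_get(config, "cluster", "n_pcs", 20))
  clusters <- knn_cluster(pcs,
                k = cfg_get(config, "cluster", "k", 15),
                resolution = cfg_get(config, "cluster", "resolution", 1.0),
                seed = stage_seed(seed, "cluster"))
  embedding <- NULL
  if (isTRUE(cfg_get(config, "cluster", "embed", FALSE)))
    embedding <- embed_2d(pcs, seed = stage_seed(seed, "embed"))

  # --- scores ---
  gene_sets <- if (!is.null(config$score$gmt)) read_gmt(config$score$gmt)
               else default_signatures()[c("naiveness", "cytotoxicity", "exhaustion")]
  scores <- score_panel(sig, gene_sets)

  # --- trajectory ---
  trajectory <- infer_trajectory(sig, clusters, scores, pcs = pcs)

  # --- tissue preference ---
  tissue_table <- tissue_preference_table(clusters, annotation)
  tissue_anova <- suppressMessages(per_patient_anova(clusters, annotation))

  # --- branch GRNs ---
  candidate_tfs <- cfg_get(config, "grn", "candidate_tfs", default_tf_list())
  min_branch_cells <- cfg_get(config, "grn", "min_branch_cells", 200)
  branches <- setdiff(levels(trajectory$branch), c("root", "trunk"))
  networks <- list(); regulon_sets <- list()
  pooled_net <- NULL; pooled_regs <- NULL
  grn_args <- function(sub, k) list(
    signatures = sub, candidate_tfs = candidate_tfs,
    n_boot = cfg_get(config, "grn", "n_boot", 20),
    support_frac = cfg_get(config, "grn", "support_frac", 0.5),
    seed = stage_seed(seed, "grn") + k,
    n_bins = config$grn$n_bins,
    n_perm = cfg_get(config, "grn", "n_perm", 1000),
    tolerance = cfg_get(config, "grn", "tolerance", 0))
  min_reg_size <- cfg_get(config, "grn", "min_regulon_size", 25)
  for (k in seq_along(branches)) {
    b <- branches[k]
    cells <- trajectory$branch == b
    if (sum(cells) < min_branch_cells) {
      # below GRN minimums: one pooled all-cells network, built once
      message(sprintf("run_pipeline: branch %s has %d cell(s) < %d; using pooled network",
                      b, sum(cells), min_branch_cells))
      if (is.null(pooled_net)) {
        pooled_net <- suppressMessages(do.call(bootstrap_consensus, grn_args(sig, 0L)))
        pooled_regs <- suppressMessages(assemble_regulons(pooled_net, sig, min_reg_size))
      }
      networks[[b]] <- pooled_net
      regulon_sets[[b]] <- pooled_regs
      attr(networks[[b]], "pooled") <- TRUE
    } else {
      sub <- sig[, cells, drop = FALSE]
      sub <- sub[apply(sub, 1, sd) > 0, , drop = FALSE]
      net <- suppressMessages(do.call(bootstrap_consensus, grn_args(sub, k)))
      networks[[b]] <- net
      regulon_sets[[b]] <- suppressMessages(assemble_regulons(net, sub, min_reg_size))
    }
  }

  # --- activity (per network, then integrated) ---
  min_overlap <- cfg_get(config, "activity", "min_overlap", 10)
  activities <- list()
  for (b in branches) {
    if (!length(regulon_sets[[b]])) next
    prov <- if (isTRUE(attr(networks[[b]], "pooled"))) "pooled" else b
    if (prov %in% names(activities)) next   # pooled network scored once
    activities[[prov]] <- suppressMessages(
      viper_matrix(sig, regulon_sets[[b]], min_overlap, provenance = prov))
  }
  integrated <- if (length(activities)) metaviper_integrate(unname(activities)) else NULL

  # --- branch signatures and regulon ranking ---
  rankings <- list(); masters <- list(); branch_grns <- list()
  for (b in branches) {
    if (!length(regulon_sets[[b]])) next
    bsig <- tryCatch(branch_signature(em, trajectory$branch, b),
                     scregulon_size_error = function(e) NULL)
    if (is.null(bsig)) next
    rk <- tryCatch(suppressMessages(rank_regulons(bsig, regulon_sets[[b]], min_overlap)),
                   scregulon_overlap_error = function(e) NULL)
    if (is.null(rk)) next
    rankings[[b]] <- rk
    ms <- select_masters(rk,
            q_max = cfg_get(config, "rank", "q_max", 0.05),
            min_size = cfg_get(config, "rank", "min_size", 25),
            top_k = cfg_get(config, "rank", "top_k", 3))
    masters[[b]] <- ms
    if (length(ms)) branch_grns[[b]] <- export_branch_grn(ms, regulon_sets[[b]], bsig)
  }

  all_masters <- unique(unlist(masters))
  report <- if (length(all_masters) && !is.null(integrated))
    expression_vs_activity_report(all_masters, em, integrated,
                                  trajectory$branch, annotation$tissue,
                                  cytotox_score = scores$cytotoxicity) else NULL

  res <- structure(list(
    config = config, dataset = ds, em = em, signatures = sig, pcs = pcs,
    clusters = clusters, embedding = embedding, scores = scores,
    trajectory = trajectory, tissue_table = tissue_table,
    tissue_anova = tissue_anova, networks = networks,
    regulon_sets = regulon_sets, activities = activities,
    integrated_activity = integrated, rankings = rankings,
    masters = masters, branch_grns = branch_grns, report = report),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @method print pipeline_result
#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d cells, %d cluster(s), root=%s\n",
              length(x$em$cell_ids), length(levels(x$clusters)),
              x$trajectory$root))
  for (b in names(x$masters))
    cat(sprintf("  %s masters: %s\n", b,
                if (length(x$masters[[b]])) paste(x$masters[[b]], collapse = ", ")
                else "(none)"))
  invisible(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write all pipeline tables and a manifest
#'
#' @param res a \code{pipeline_result}.
#' @param out_dir output directory.
#' @return Paths written, invisibly.
#' @export
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tr <- res$trajectory
  paths <- c(paths, write_tsv(data.frame(
    cell_id = res$em$cell_ids,
    cluster = as.character(res$clusters),
    component1 = tr$components[, 1], component2 = tr$components[, 2],
    pseudotime = tr$pseudotime, branch = as.character(tr$branch)),
    file.path(out_dir, "cells.tsv")))
  paths <- c(paths, write_tsv(tr$backbone$edges, file.path(out_dir, "backbone.tsv")))
  paths <- c(paths, write_tsv(res$scores, file.path(out_dir, "scores.tsv")))
  paths <- c(paths, write_tsv(res$tissue_table, file.path(out_dir, "tissue_preference.tsv")))
  paths <- c(paths, write_tsv(res$tissue_anova, file.path(out_dir, "tissue_anova.tsv")))
  if (!is.null(res$embedding))
    paths <- c(paths, write_tsv(data.frame(cell_id = rownames(res$embedding),
                                           res$embedding),
                                file.path(out_dir, "embedding.tsv")))
  for (b in names(res$regulon_sets)) {
    if (!length(res$regulon_sets[[b]])) next
    p <- file.path(out_dir, paste0("regulons_", b, ".tsv"))
    write_regulon_table(res$regulon_sets[[b]], p)
    paths <- c(paths, p)
  }
  if (!is.null(res$integrated_activity))
    paths <- c(paths, write_tsv(
      data.frame(tf = rownames(res$integrated_activity), res$integrated_activity,
                 check.names = FALSE),
      file.path(out_dir, "activity.tsv")))
  for (b in names(res$rankings))
    paths <- c(paths, write_tsv(as.data.frame(res$rankings[[b]]),
                                file.path(out_dir, paste0("ranking_", b, ".tsv"))))
  if (length(res$masters)) {
    md <- do.call(rbind, lapply(names(res$masters), function(b)
      if (length(res$masters[[b]]))
        data.frame(branch = b, tf = res$masters[[b]]) else NULL))
    if (!is.null(md))
      paths <- c(paths, write_tsv(md, file.path(out_dir, "masters.tsv")))
  }
  for (b in names(res$branch_grns))
    paths <- c(paths, write_tsv(res$branch_grns[[b]],
                                file.path(out_dir, paste0("branch_grn_", b, ".tsv"))))
  manifest <- list(seed = res$config$seed,
                   config = res$config[setdiff(names(res$config), "seed")],
                   files = as.list(tools::md5sum(sort(paths))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(paths)
}
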