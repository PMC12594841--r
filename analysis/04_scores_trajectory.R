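#!/usr/bin/env Rscript
# Stage 4 — phenotype scores (naiveness / cytotoxicity / exhaustion),
# the root-trunk-branch trajectory with per-cell pseudotime, the
# score-component Pearson correlations and LOESS trend fits.

source("analysis/common.R")

p <- load_processed()
clusters <- knn_cluster(p$pcs, seed = SEED)
scores <- suppressMessages(score_panel(p$signatures))
tr <- infer_trajectory(p$signatures, clusters, scores, pcs = p$pcs)

cat("root cluster:", tr$root, "\n")
cat("branch sizes:\n"); print(table(tr$branch))

write_tsv(data.frame(cell_id = p$em$cell_ids, scores[-1],
                     component1 = tr$components[, 1],
                     component2 = tr$components[, 2],
                     pseudotime = tr$pseudotime,
                     branch = as.character(tr$branch)),
          "scores_trajectory.tsv")
write_tsv(tr$backbone$edges, "backbone.tsv")

cors <- score_component_correlation(scores, tr$components)
write_tsv(cors, "score_component_correlations.tsv")
cat("score-component correlations:\n"); print(cors, row.names = FALSE)

loess_tabs <- lapply(c("naiveness", "cytotoxicity", "exhaustion"), function(s) {
  f <- loess_fit(tr$components[, 2], scores[[s]], span = 0.5)
  data.frame(score = s, component = "component2", f)
})
write_tsv(do.call(rbind, loess_tabs), "loess_fits.tsv")

proj <- branch_axis_projection(tr, "effector")
ct <- cor.test(proj, scores$cytotoxicity)
nt <- cor.test(proj, scores$naiveness)
cat(sprintf("effector axis: cytotoxicity r = %.2f (p = %.2g), naiveness r = %.2f (p = %.2g)\n",
            ct$estimate, ct$p.value, nt$estimate, nt$p.value))
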