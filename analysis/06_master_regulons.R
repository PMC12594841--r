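#!/usr/bin/env Rscript
# Stage 6 — branch-specific master regulons: rank-sum branch signatures,
# aREA enrichment ranking of the regulons with BH FDR, master selection and
# the branch GRN + expression/activity contrast for the winners.

source("analysis/common.R")

p <- load_processed()
clusters <- knn_cluster(p$pcs, seed = SEED)
scores <- suppressMessages(score_panel(p$signatures))
tr <- infer_trajectory(p$signatures, clusters, scores, pcs = p$pcs)
net <- suppressMessages(bootstrap_consensus(p$signatures, default_tf_list(),
                                            n_boot = 20, seed = SEED))
regs <- suppressMessages(assemble_regulons(net, p$signatures, 25))
am <- suppressMessages(viper_matrix(p$signatures, regs, provenance = "pooled"))

branches <- setdiff(levels(tr$branch), c("root", "trunk"))
all_masters <- character(0)
for (b in branches) {
  bsig <- tryCatch(branch_signature(p$em, tr$branch, b),
                   scregulon_size_error = function(e) NULL)
  if (is.null(bsig)) next
  rk <- suppressMessages(rank_regulons(bsig, regs))
  write_tsv(as.data.frame(rk), paste0("ranking_", b, ".tsv"))
  ms <- select_masters(rk)
  all_masters <- union(all_masters, ms)
  cat(sprintf("%s branch: top regulons %s; masters: %s\n", b,
              paste(head(rk$tf, 3), collapse = ", "),
              if (length(ms)) paste(ms, collapse = ", ") else "(none)"))
  if (length(ms))
    write_tsv(export_branch_grn(ms, regs, bsig), paste0("branch_grn_", b, ".tsv"))
}

if (length(all_masters)) {
  rep_out <- expression_vs_activity_report(all_masters, p$em, am, tr$branch,
                                           p$annotation$tissue,
                                           cytotox_score = scores$cytotoxicity)
  write_tsv(rep_out$by_branch, "masters_by_branch.tsv")
  write_tsv(rep_out$by_tissue, "masters_by_tissue.tsv")
  write_tsv(rep_out$expression_correlation, "masters_expression_cytotox.tsv")
  cat("expression vs activity by branch for the selected masters:\n")
  print(rep_out$by_branch, row.names = FALSE)
}
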