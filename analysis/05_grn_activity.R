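#!/usr/bin/env Rscript
# Stage 5 — regulatory-network inference (bootstrap-consensus MI + DPI) and
# per-cell protein activity (aREA NES), checked against the planted truth.

source("analysis/common.R")

p <- load_processed()
ds_truth <- read_regulon_table(file.path(DATA_DIR, "regulons.tsv"))
activity_true <- read.delim(file.path(DATA_DIR, "activity.tsv"),
                            check.names = FALSE)

net <- suppressMessages(bootstrap_consensus(p$signatures, default_tf_list(),
                                            n_boot = 20, seed = SEED))
cat("consensus network:", nrow(net$edges), "edges over",
    length(unique(net$edges$tf)), "TFs\n")
regs <- suppressMessages(assemble_regulons(net, p$signatures, 25))
write_regulon_table(regs, file.path(OUT_DIR, "regulons_inferred.tsv"))
message("wrote ", file.path(OUT_DIR, "regulons_inferred.tsv"))

f1 <- sapply(names(ds_truth), function(tf) {
  if (is.null(regs[[tf]])) return(0)
  inf <- regs[[tf]]$target; tru <- ds_truth[[tf]]$target
  2 * length(intersect(inf, tru)) / (length(inf) + length(tru))
})
cat("per-TF target-recovery F1:\n"); print(round(f1, 2))
cat("median F1:", round(median(f1), 3), "\n")

am <- suppressMessages(viper_matrix(p$signatures, regs, provenance = "pooled"))
write_tsv(data.frame(tf = rownames(am), am, check.names = FALSE),
          "activity_nes.tsv")

tru_act <- as.matrix(activity_true[, -1])
rownames(tru_act) <- activity_true$tf
sp <- sapply(intersect(rownames(am), rownames(tru_act)), function(tf)
  cor(am[tf, ], tru_act[tf, colnames(am)], method = "spearman"))
cat("NES vs planted activity (Spearman):\n"); print(round(sp, 2))
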