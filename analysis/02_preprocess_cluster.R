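#!/usr/bin/env Rscript
# Stage 2 — QC filtering, log-normalization, per-cell z-score signatures,
# mutual-kNN modularity clustering in 20-PC space, and the t-SNE map used
# for reporting.

source("analysis/common.R")

p <- load_processed()
cat("after filtering:", nrow(p$signatures), "genes x", ncol(p$signatures), "cells\n")

clusters <- knn_cluster(p$pcs, k = 15, resolution = 1.0, seed = SEED)
cat("found", length(levels(clusters)), "clusters; sizes:\n")
print(table(clusters))

tsne <- embed_2d(p$pcs, seed = SEED)

write_tsv(data.frame(cell_id = p$em$cell_ids,
                     cluster = as.character(clusters),
                     tsne1 = tsne[, 1], tsne2 = tsne[, 2]),
          "clusters_embedding.tsv")
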