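#!/usr/bin/env Rscript
# Stage 3 — tissue preference per cluster: the observed/expected ratio
# R_O/E (cluster x tissue), enrichment calls (strong at >= 2.5), and a
# per-patient one-way ANOVA of the tissue effect.

source("analysis/common.R")

p <- load_processed()
clusters <- knn_cluster(p$pcs, seed = SEED)

tab <- tissue_preference_table(clusters, p$annotation)
anova_tab <- suppressMessages(per_patient_anova(clusters, p$annotation))
tab$anova_p <- anova_tab$p[match(tab$cluster, anova_tab$cluster)]
write_tsv(tab, "tissue_preference.tsv")

enr <- tab[tab$call == "enriched", ]
cat("tissue-enriched cluster/tissue pairs (R_O/E > 1):\n")
print(enr[order(-enr$roe), c("cluster", "tissue", "roe", "strong", "anova_p")],
      row.names = FALSE)
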