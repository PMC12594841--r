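#!/usr/bin/env Rscript
# Stage 1 — simulate the reference dataset: 600 CD8+-like cells from 5
# patients across blood/normal/tumor, a five-segment developmental topology
# (naive root, memory trunk, effector / exhausted / dysfunctional branches)
# and 6 planted TF regulons (40 signed targets each, effect 1.5) driving
# negative-binomial counts. Ground truth is written alongside the counts.

source("analysis/common.R")

cfg <- sim_config(seed = SEED)
ds <- simulate_dataset(cfg)
write_dataset(ds, DATA_DIR)

cat("dataset:", nrow(ds$counts), "genes x", ncol(ds$counts), "cells\n")
cat("segment sizes:\n"); print(table(ds$truth$segment))
cat("tissue sizes:\n"); print(table(ds$truth$tissue))
cat("planted drivers:\n"); print(ds$truth$driven_segment)
cat("median library size:", median(colSums(ds$counts)), "counts/cell\n")
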