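# Shared bits for the numbered analysis scripts: one seed, one data
# directory, and the preprocessing steps every later stage needs.

library(scregulon)

SEED <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)

# read the simulated dataset back through the package's own readers and
# rebuild the derived layers (cheap; keeps every script self-contained)
load_processed <- function() {
  em <- read_counts(DATA_DIR, "mtx")
  ann <- read_annotation(file.path(DATA_DIR, "annotation.tsv"), em$cell_ids)
  em <- filter_expression(em)
  ann <- ann[match(em$cell_ids, ann$cell_id), ]
  em <- normalize_log(em)
  sig <- suppressMessages(single_cell_signatures(em))
  list(em = em, annotation = ann, signatures = sig,
       pcs = pca_reduce(sig, 20))
}

write_tsv <- function(df, name) {
  path <- file.path(OUT_DIR, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
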