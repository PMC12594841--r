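# Readers and writers for every on-disk format the pipeline touches:
# Matrix Market counts with TSV sidecars, annotation TSV, GMT gene sets,
# regulon tables and the YAML run configuration.
#
# Canonical orientation is genes-as-rows (the Matrix Market sidecar
# convention: genes.tsv describes rows, barcodes.tsv describes columns).
# Gene identifier matching is case-sensitive exact string match throughout;
# `case_fold = TRUE` options exist where mouse/human symbol reuse matters.

#' Construct an expression matrix container
#'
#' Bundles a genes x cells count matrix with its identifiers and any derived
#' layers (log-normalized, z-scored). The count matrix may be dense or a
#' sparse \code{Matrix::dgCMatrix}.
#'
#' @param counts genes x cells non-negative numeric matrix.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell identifiers (columns).
#' @param layers named list of derived matrices with the same shape.
#' @return An object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(counts, gene_ids = rownames(counts),
                              cell_ids = colnames(counts), layers = list()) {
  if (is.null(gene_ids) || is.null(cell_ids))
    sc_stop("gene_ids and cell_ids are required")
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids))
    sc_stop(sprintf("dimension mismatch: counts %d x %d vs %d gene ids, %d cell ids",
                    nrow(counts), ncol(counts), length(gene_ids), length(cell_ids)),
            "scregulon_format_error")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    sc_stop(paste0("duplicate gene id(s): ", paste(unique(dup), collapse = ", ")),
            "scregulon_format_error")
  dup <- cell_ids[duplicated(cell_ids)]
  if (length(dup))
    sc_stop(paste0("duplicate cell id(s): ", paste(unique(dup), collapse = ", ")),
            "scregulon_format_error")
  if (any(counts < 0)) sc_stop("counts must be non-negative")
  dimnames(counts) <- list(gene_ids, cell_ids)
  for (nm in names(layers)) {
    if (!all(dim(layers[[nm]]) == dim(counts)))
      sc_stop(paste0("layer '", nm, "' shape differs from counts"))
    dimnames(layers[[nm]]) <- dimnames(counts)
  }
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 layers = layers),
            class = "expression_matrix")
}

#' @method print expression_matrix
#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells; layers: %s\n",
              length(x$gene_ids), length(x$cell_ids),
              if (length(x$layers)) paste(names(x$layers), collapse = ", ") else "none"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Read a count matrix
#'
#' Reads either a Matrix Market directory (\code{matrix.mtx} plus
#' \code{genes.tsv} and \code{barcodes.tsv} sidecars) or a dense TSV with gene
#' ids in the first column and cell ids in the header. Orientation is
#' genes x cells; for Matrix Market input the sidecar lengths disambiguate and
#' the matrix is auto-transposed when rows match barcodes and columns match
#' genes.
#'
#' @param path directory containing the .mtx triplet, or a TSV file path.
#' @param format \code{"mtx"} or \code{"tsv"}.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf))
      if (!file.exists(f)) sc_stop(paste0("missing file: ", f), "scregulon_io_error")
    m <- Matrix::readMM(mtx)
    genes <- read.delim(gf, header = FALSE, colClasses = "character")[[1]]
    cells <- read.delim(bf, header = FALSE, colClasses = "character")[[1]]
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      # canonical orientation
    } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      m <- Matrix::t(m)
    } else {
      sc_stop(sprintf(
        "sidecar mismatch: matrix is %d x %d but genes.tsv has %d rows and barcodes.tsv has %d rows",
        nrow(m), ncol(m), length(genes), length(cells)), "scregulon_format_error")
    }
    expression_matrix(methods::as(m, "CsparseMatrix"), genes, cells)
  } else {
    if (!file.exists(path)) sc_stop(paste0("missing file: ", path), "scregulon_io_error")
    df <- read.delim(path, check.names = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    expression_matrix(m, genes, colnames(df)[-1])
  }
}

#' Write a count matrix as a Matrix Market triplet
#'
#' Emits \code{matrix.mtx}, \code{genes.tsv} and \code{barcodes.tsv} into
#' \code{dir}. Integer counts survive the round trip exactly.
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param dir output directory (created if absent).
#' @export
write_counts <- function(em, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(em$counts, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(em$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(em$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a cell annotation table
#'
#' TSV with header columns \code{cell_id}, \code{tissue}, \code{patient} and
#' optionally \code{segment} and/or \code{cluster}.
#'
#' @param path TSV file.
#' @param cell_ids optional character vector; when given, the annotation must
#'   cover exactly this cell set (set equality) and is reordered to match.
#' @return data.frame of the annotation.
#' @export
read_annotation <- function(path, cell_ids = NULL) {
  ann <- read.delim(path, colClasses = "character")
  need <- c("cell_id", "tissue", "patient")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    sc_stop(paste0("annotation missing column(s): ", paste(miss, collapse = ", ")),
            "scregulon_format_error")
  if (!is.null(cell_ids)) {
    if (!setequal(ann$cell_id, cell_ids))
      sc_stop(sprintf("annotation covers %d cells but matrix has %d; sets differ",
                      length(unique(ann$cell_id)), length(cell_ids)),
              "scregulon_format_error")
    ann <- ann[match(cell_ids, ann$cell_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  ann
}

#' Read gene signature sets in GMT format
#'
#' Tab-separated lines: set name, description (may be empty or NA), then gene
#' ids. Duplicate genes within a line are removed with a warning.
#'
#' @param path GMT file.
#' @param case_fold lowercase-fold gene symbols (for mouse/human symbol reuse).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path, case_fold = FALSE) {
  if (!file.exists(path)) sc_stop(paste0("missing file: ", path), "scregulon_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      sc_stop(sprintf("GMT line %d has %d field(s); at least 3 required", i, length(f)),
              "scregulon_format_error")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (case_fold) genes <- tolower(genes)
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': %d duplicate gene(s) removed",
                      f[1], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    if (!length(genes))
      sc_stop(sprintf("GMT line %d ('%s') has no genes", i, f[1]),
              "scregulon_format_error")
    sets[[f[1]]] <- genes
  }
  sets
}

#' Write gene signature sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "NA", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Default phenotype gene signatures
#'
#' The shipped naiveness / cytotoxicity / exhaustion sets built from the
#' canonical CD8+ T-cell markers (cytotoxicity: GNLY, GZMB, PRF1; exhaustion /
#' inhibitory receptors: HAVCR2, TIGIT, PDCD1; naiveness: LEF1, TCF7, SELL,
#' CCR7), plus the murine terminal-effector signature (Ccl3, Cx3cr1, Gzma,
#' Gzmb, Klra3, Klrg1, Prdm1, S1pr5).
#'
#' @return Named list of gene-id vectors.
#' @export
default_signatures <- function() {
  read_gmt(system.file("extdata", "signatures_default.gmt",
                       package = "scregulon", mustWork = TRUE))
}

#' Shipped candidate transcription-factor list
#'
#' Regulator universe used by network inference when no candidate list is
#' supplied: a compact curated set of T-cell differentiation TFs.
#'
#' @return Character vector of TF symbols.
#' @export
default_tf_list <- function() {
  readLines(system.file("extdata", "tf_symbols.txt",
                        package = "scregulon", mustWork = TRUE))
}

#' Read a regulon table
#'
#' TSV with header columns \code{tf}, \code{target}, \code{mode},
#' \code{likelihood}. Modes outside [-1, 1] or likelihoods outside (0, 1] are
#' format errors (no clipping). A missing likelihood column defaults to 1.0
#' for all rows, with a warning.
#'
#' @param path TSV file.
#' @return A \code{regulon_set} (see \code{\link{regulon_set}}).
#' @export
read_regulon_table <- function(path) {
  df <- read.delim(path)
  need <- c("tf", "target", "mode")
  miss <- setdiff(need, names(df))
  if (length(miss))
    sc_stop(paste0("regulon table missing column(s): ", paste(miss, collapse = ", ")),
            "scregulon_format_error")
  if (!"likelihood" %in% names(df)) {
    warning("regulon table has no likelihood column; defaulting to 1.0")
    df$likelihood <- 1.0
  }
  regulon_set_from_table(df)
}

#' Write a regulon set as a regulon table TSV
#' @param rs a \code{regulon_set}.
#' @param path output TSV.
#' @export
write_regulon_table <- function(rs, path) {
  df <- regulon_table(rs)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a regulon set
#'
#' A regulon is a transcription factor together with signed target modes
#' (mode in [-1, 1]: sign = direction of regulation) and confidence weights
#' (likelihood in (0, 1]). Duplicate (tf, target) pairs are an error.
#'
#' @param regulons named list (by TF) of data.frames with columns
#'   \code{target}, \code{mode}, \code{likelihood}.
#' @return Object of class \code{regulon_set}.
#' @export
regulon_set <- function(regulons) {
  for (tf in names(regulons)) {
    r <- regulons[[tf]]
    if (!all(c("target", "mode", "likelihood") %in% names(r)))
      sc_stop(paste0("regulon '", tf, "' needs target/mode/likelihood columns"))
    if (anyDuplicated(r$target))
      sc_stop(paste0("regulon '", tf, "' has duplicate target(s): ",
                     paste(unique(r$target[duplicated(r$target)]), collapse = ", ")),
              "scregulon_format_error")
    if (any(r$mode < -1 | r$mode > 1))
      sc_stop(paste0("regulon '", tf, "': mode outside [-1, 1]"),
              "scregulon_format_error")
    if (any(r$likelihood <= 0 | r$likelihood > 1))
      sc_stop(paste0("regulon '", tf, "': likelihood outside (0, 1]"),
              "scregulon_format_error")
    if (tf %in% r$target)
      sc_stop(paste0("regulon '", tf, "' contains itself as a target"),
              "scregulon_format_error")
  }
  structure(regulons, class = "regulon_set")
}

regulon_set_from_table <- function(df) {
  key <- paste(df$tf, df$target, sep = "\r")
  if (anyDuplicated(key))
    sc_stop("duplicate (tf, target) pair(s) in regulon table", "scregulon_format_error")
  if (any(df$mode < -1 | df$mode > 1))
    sc_stop(sprintf("mode outside [-1, 1] (e.g. %g)", df$mode[which(df$mode < -1 | df$mode > 1)[1]]),
            "scregulon_format_error")
  if (any(df$likelihood <= 0 | df$likelihood > 1))
    sc_stop("likelihood outside (0, 1]", "scregulon_format_error")
  regs <- lapply(split(df, df$tf), function(d) {
    data.frame(target = as.character(d$target), mode = d$mode,
               likelihood = d$likelihood, row.names = NULL)
  })
  regulon_set(regs)
}

#' Flatten a regulon set to a table
#' @param rs a \code{regulon_set}.
#' @return data.frame with columns tf, target, mode, likelihood.
#' @export
regulon_table <- function(rs) {
  do.call(rbind, lapply(names(rs), function(tf) {
    r <- rs[[tf]]
    data.frame(tf = tf, target = r$target, mode = r$mode,
               likelihood = r$likelihood, row.names = NULL)
  }))
}

#' @method print regulon_set
#' @export
print.regulon_set <- function(x, ...) {
  sizes <- vapply(x, nrow, integer(1))
  cat(sprintf("regulon_set: %d regulon(s); sizes %s\n", length(x),
              paste(range(sizes), collapse = "-")))
  invisible(x)
}

#' Read the YAML run configuration
#'
#' Unknown top-level or per-stage keys are rejected by
#' \code{\link{validate_run_config}} at run time.
#'
#' @param path YAML file.
#' @return Nested list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
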