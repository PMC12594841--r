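#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov cor cor.test loess median p.adjust pnorm predict
#'   prcomp qnorm quantile rbinom rgamma rlnorm rmultinom rnbinom rnorm runif
#'   sd setNames var dist
#' @importFrom utils read.delim write.table head
NULL

# stop() with a consistent error class so callers/tests can match on it
sc_stop <- function(msg, class = "scregulon_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# row-wise sd without apply() overhead
row_sds <- function(m) {
  n <- ncol(m)
  if (n < 2L) sc_stop("at least 2 columns required to compute row sds")
  mu <- Matrix::rowMeans(m)
  sqrt(pmax(Matrix::rowMeans(m * m) - mu^2, 0) * n / (n - 1))
}

# Spearman correlation of two numeric vectors (wrapper kept for readability)
spearman <- function(x, y) suppressWarnings(stats::cor(x, y, method = "spearman"))

# deterministic per-stage seed fan-out from a single global seed
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, preprocess = 23L, grn = 37L, activity = 53L,
               cluster = 71L, tissue = 89L, score = 97L, trajectory = 113L,
               rank = 131L, embed = 149L)
  if (!stage %in% names(offsets)) sc_stop(paste0("unknown stage: ", stage))
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}
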