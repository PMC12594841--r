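# Mutual information, permutation threshold, DPI pruning, bootstrap
# consensus and regulon assembly.

test_that("perfect dependence on a divisible grid gives log(n_bins)", {
  x <- rnorm(400)
  expect_equal(mutual_information(x, x, n_bins = 4), log(4), tolerance = 1e-12)
  expect_equal(mutual_information(x, 2 * x + 7, n_bins = 4), log(4),
               tolerance = 1e-12)
})

test_that("independent permutations have near-zero MI at large n", {
  set.seed(1)
  x <- rnorm(1e4); y <- sample(x)
  expect_lt(mutual_information(x, y), 0.01)
})

test_that("constant input yields zero MI with a warning; contracts enforced", {
  expect_warning(mi <- mutual_information(rep(1, 20), rnorm(20)), "constant")
  expect_equal(mi, 0)
  expect_error(mutual_information(rnorm(10), rnorm(11)), "mismatch")
  expect_error(mutual_information(rnorm(5), rnorm(5)), "10")
})

test_that("MI is symmetric and invariant to monotone transforms (property)", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(200); y <- x + rnorm(200)
    m <- mutual_information(x, y, 5)
    expect_equal(mutual_information(y, x, 5), m, tolerance = 1e-12)
    expect_equal(mutual_information(exp(x), y^3 + 2 * y, 5), m, tolerance = 1e-12)
  }
})

test_that("alpha = 1 returns the null minimum and thresholds are reproducible", {
  set.seed(3)
  sig <- matrix(rnorm(20 * 100), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
  set.seed(7); t1 <- mi_null_threshold(sig, n_perm = 100, alpha = 1)
  set.seed(7); t1b <- mi_null_threshold(sig, n_perm = 100, alpha = 1)
  set.seed(7); tmax <- mi_null_threshold(sig, n_perm = 100, alpha = 1e-6)
  expect_identical(t1, t1b)
  expect_lte(t1, tmax)
})

test_that("the null threshold concentrates downward as n grows", {
  # estimator concentration: more cells -> smaller null MI quantile
  wins <- 0
  for (r in 1:10) {
    set.seed(100 + r)
    s_small <- matrix(rnorm(15 * 100), nrow = 15,
                      dimnames = list(sprintf("g%02d", 1:15), NULL))
    s_big <- matrix(rnorm(15 * 1000), nrow = 15,
                    dimnames = list(sprintf("g%02d", 1:15), NULL))
    thr_s <- mi_null_threshold(s_small, n_perm = 100, alpha = 0.05, n_bins = 4)
    thr_b <- mi_null_threshold(s_big, n_perm = 100, alpha = 0.05, n_bins = 4)
    wins <- wins + (thr_b < thr_s)
  }
  expect_gte(wins, 9)
})

test_that("DPI removes the strict triangle minimum and nothing else", {
  edges <- data.frame(tf = c("A", "A", "B"), target = c("B", "C", "C"),
                      mi = c(0.5, 0.1, 0.4))
  net <- mi_network(edges, candidate_tfs = c("A", "B"), n_cells = 100)
  pruned <- apply_dpi(net, 0)
  expect_equal(nrow(pruned$edges), 2)
  expect_false(any(pruned$edges$tf == "A" & pruned$edges$target == "C"))
  # triangle-free network is untouched
  e2 <- data.frame(tf = c("A", "A"), target = c("C", "D"), mi = c(0.3, 0.2))
  n2 <- mi_network(e2, "A", 100)
  expect_equal(apply_dpi(n2, 0)$edges, n2$edges)
})

test_that("DPI equals the exhaustive triangle oracle on random networks", {
  for (s in 1:200) {
    set.seed(s)
    n_nodes <- sample(5:25, 1)
    tfs <- paste0("T", 1:3)
    nodes <- c(tfs, paste0("g", seq_len(n_nodes - 3)))
    cand <- expand.grid(tf = tfs, target = nodes, stringsAsFactors = FALSE)
    cand <- cand[cand$tf != cand$target, ]
    # drop duplicate unordered pairs (tf-tf edges appear twice)
    unord <- paste(pmin(cand$tf, cand$target), pmax(cand$tf, cand$target))
    cand <- cand[!duplicated(unord), ]
    keep <- runif(nrow(cand)) < 0.5
    edges <- cand[keep, , drop = FALSE]
    if (!nrow(edges)) next
    edges$mi <- round(runif(nrow(edges), 0.01, 1), 3)
    net <- mi_network(edges, tfs, 100)
    got <- apply_dpi(net, 0)$edges
    want <- oracle_dpi(edges, 0)
    key <- function(d) sort(paste(pmin(d$tf, d$target), pmax(d$tf, d$target)))
    expect_identical(key(got), key(want))
  }
})

test_that("degenerate bootstrap equals a single seeded resample", {
  ds <- cached_dataset(1)
  sig <- prep_signatures(ds)[1:80, 1:150]
  tfs <- intersect(default_tf_list(), rownames(sig))
  net1 <- suppressMessages(
    bootstrap_consensus(sig, tfs, n_boot = 1, support_frac = 1, seed = 5,
                        n_perm = 100))
  set.seed(5)
  idx <- sample.int(ncol(sig), ncol(sig), replace = TRUE)
  net2 <- suppressMessages(
    infer_network(sig[, idx], tfs, n_perm = 100))
  key <- function(n) sort(paste(n$edges$tf, n$edges$target))
  expect_identical(key(net1), key(net2))
})

test_that("stricter support keeps a subset of lenient-support edges", {
  ds <- cached_dataset(1)
  sig <- prep_signatures(ds)[1:80, 1:150]
  tfs <- intersect(default_tf_list(), rownames(sig))
  loose <- suppressMessages(bootstrap_consensus(sig, tfs, n_boot = 8,
                                                support_frac = 0.5, seed = 2,
                                                n_perm = 100))
  strict <- suppressMessages(bootstrap_consensus(sig, tfs, n_boot = 8,
                                                 support_frac = 1.0, seed = 2,
                                                 n_perm = 100))
  key <- function(n) paste(n$edges$tf, n$edges$target)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("assembly signs modes by correlation and drops undersized TFs", {
  set.seed(8)
  base <- rnorm(60)
  sig <- rbind(TFX = base,
               up = base + rnorm(60, 0, 0.01),
               down = -base + rnorm(60, 0, 0.01),
               noise = rnorm(60))
  colnames(sig) <- sprintf("c%02d", 1:60)
  edges <- data.frame(tf = "TFX", target = c("up", "down"), mi = c(0.9, 0.8))
  net <- mi_network(edges, "TFX", 60)
  regs <- assemble_regulons(net, sig, min_regulon_size = 2)
  r <- regs$TFX
  expect_gt(r$mode[r$target == "up"], 0.9)
  expect_lt(r$mode[r$target == "down"], -0.9)
  expect_equal(max(r$likelihood), 1)
  expect_message(assemble_regulons(net, sig, min_regulon_size = 3), "dropping")
  expect_warning(assemble_regulons(mi_network(edges[0, ], "TFX", 60), sig),
                 "empty")
})
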