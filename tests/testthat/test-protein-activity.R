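# aREA enrichment scores, NES calibration and multi-network integration.

toy_signature <- function(n = 100, seed = 1) {
  set.seed(seed)
  setNames(rnorm(n), sprintf("g%03d", 1:n))
}

test_that("activator regulons at the top of the signature score positive", {
  sig <- sort(toy_signature(), decreasing = TRUE)
  reg <- data.frame(target = names(sig)[1:10], mode = 1, likelihood = 1)
  a <- area_es(sig, reg)
  expect_gt(a$es, 0)
  expect_equal(a$n_eff, 10)
})

test_that("negating all modes negates the enrichment score exactly", {
  sig <- toy_signature()
  reg <- data.frame(target = names(sig)[c(3, 10, 44, 71)],
                    mode = c(1, -1, 1, -1), likelihood = c(1, 0.5, 0.8, 1))
  flipped <- reg; flipped$mode <- -flipped$mode
  expect_equal(area_es(sig, flipped)$es, -area_es(sig, reg)$es, tolerance = 1e-12)
  am <- viper_matrix(cbind(c1 = sig, c2 = rev(sig)),
                     regulon_set(list(R = reg)), min_overlap = 4)
  amf <- viper_matrix(cbind(c1 = sig, c2 = rev(sig)),
                      regulon_set(list(R = flipped)), min_overlap = 4)
  expect_equal(unclass(amf), -unclass(am), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a 10-gene enrichment score matches the hand-computed weighted sum", {
  sig <- setNames(c(2.1, -1.3, 0.4, 3.2, -0.8, 0.0, 1.1, -2.2, 0.9, -0.1),
                  letters[1:10])
  reg <- data.frame(target = c("a", "d", "h"), mode = c(1, 0.5, -1),
                    likelihood = c(1, 0.6, 0.8))
  # independent recomputation from the definition
  q <- rank(sig) / (length(sig) + 1)
  t2 <- qnorm(q); t1 <- qnorm(0.5 + abs(q - 0.5))
  w <- reg$likelihood
  contrib <- reg$mode * t2[reg$target] + (1 - abs(reg$mode)) * t1[reg$target]
  es_hand <- sum(w * contrib) / sum(w)
  a <- area_es(sig, reg)
  expect_equal(a$es, es_hand, tolerance = 1e-12)
  expect_equal(a$n_eff, sum(w)^2 / sum(w^2), tolerance = 1e-12)
})

test_that("missing overlap raises a named error", {
  sig <- toy_signature()
  reg <- data.frame(target = c("absent1", "absent2"), mode = 1, likelihood = 1)
  expect_error(area_es(sig, reg, tf = "TFQ"), "TFQ",
               class = "scregulon_overlap_error")
})

test_that("NES respects effective regulon size, collapsing duplicates", {
  expect_equal(nes_from_es(1.3, 1), 1.3)
  sig <- toy_signature()
  single <- data.frame(target = "g007", mode = 1, likelihood = 0.7)
  doubled <- rbind(single, single)
  a1 <- area_es(sig, single); a2 <- area_es(sig, doubled)
  expect_equal(nes_from_es(a2$es, a2$n_eff), nes_from_es(a1$es, a1$n_eff),
               tolerance = 1e-12)
})

test_that("the matrix path equals per-cell composition", {
  sig <- cbind(c1 = toy_signature(50, 1), c2 = toy_signature(50, 2),
               c3 = toy_signature(50, 3))
  reg <- data.frame(target = rownames(sig)[c(2, 9, 17, 30, 44)],
                    mode = c(1, 1, -1, 0.5, -0.2),
                    likelihood = c(1, 0.9, 0.8, 1, 0.6))
  am <- viper_matrix(sig, regulon_set(list(R = reg)), min_overlap = 5)
  for (j in 1:3) {
    a <- area_es(sig[, j], reg)
    expect_equal(unname(am["R", j]), nes_from_es(a$es, a$n_eff),
                 tolerance = 1e-12)
  }
})

test_that("NES is null-calibrated on random regulons", {
  set.seed(1)
  genes <- sprintf("g%04d", 1:2000)
  sig <- setNames(rnorm(2000), genes)
  draws <- replicate(1000, {
    sz <- sample(25:100, 1)
    reg <- data.frame(target = sample(genes, sz),
                      mode = sample(c(-1, 1), sz, TRUE),
                      likelihood = runif(sz, 0.5, 1))
    a <- area_es(sig, reg)
    nes_from_es(a$es, a$n_eff)
  })
  expect_gt(mean(draws), -0.1); expect_lt(mean(draws), 0.1)
  expect_gt(sd(draws), 0.9); expect_lt(sd(draws), 1.1)
})

test_that("permuted signatures give near-null activity rows", {
  set.seed(4)
  sig <- matrix(rnorm(300 * 200), nrow = 300,
                dimnames = list(sprintf("g%03d", 1:300), sprintf("c%03d", 1:200)))
  regs <- regulon_set(lapply(setNames(nm = paste0("R", 1:10)), function(nm) {
    data.frame(target = sample(rownames(sig), 30),
               mode = sample(c(-1, 1), 30, TRUE), likelihood = 1)
  }))
  am <- viper_matrix(sig, regs)
  expect_true(all(abs(rowMeans(am)) < 0.2))
})

test_that("activity recovers planted TF activities on default data", {
  ds <- cached_dataset(1)
  sig <- prep_signatures(ds)
  am <- suppressMessages(viper_matrix(sig, ds$truth$regulons))
  sp <- vapply(rownames(am), function(tf)
    cor(am[tf, ], ds$truth$tf_activity[tf, colnames(am)], method = "spearman"),
    numeric(1))
  expect_gte(median(sp), 0.6)
})

test_that("integration is identity for one network and sqrt(2)-scaled for twins", {
  sig <- cbind(c1 = toy_signature(80, 5), c2 = toy_signature(80, 6))
  reg <- regulon_set(list(R = data.frame(target = rownames(sig)[1:20],
                                         mode = 1, likelihood = 1)))
  am <- viper_matrix(sig, reg, min_overlap = 5)
  expect_equal(unclass(metaviper_integrate(list(am))), unclass(am))
  twin <- metaviper_integrate(list(am, am))
  expect_equal(unclass(twin), sqrt(2) * unclass(am), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("disjoint cell sets fail to integrate", {
  m1 <- structure(matrix(1, 1, 2, dimnames = list("R", c("a", "b"))),
                  class = c("activity_matrix", "matrix"))
  m2 <- structure(matrix(1, 1, 2, dimnames = list("R", c("c", "d"))),
                  class = c("activity_matrix", "matrix"))
  expect_error(metaviper_integrate(list(m1, m2)),
               class = "scregulon_alignment_error")
})

test_that("an uninformative network degrades integration gracefully", {
  ds <- cached_dataset(1, tf_self_expression = FALSE)
  sig <- prep_signatures(ds)
  truth <- ds$truth
  am <- suppressMessages(viper_matrix(sig, truth$regulons))
  set.seed(5)
  perm <- lapply(truth$regulons, function(r) {
    r$target <- sample(setdiff(rownames(sig), names(truth$regulons)), nrow(r)); r
  })
  am_p <- suppressMessages(viper_matrix(sig, regulon_set(perm),
                                        provenance = "permuted"))
  med_cor <- function(m) median(vapply(rownames(m), function(tf)
    cor(m[tf, ], truth$tf_activity[tf, colnames(m)], method = "spearman"),
    numeric(1)))
  int <- metaviper_integrate(list(am, am_p))
  expect_gte(med_cor(int), 0.8 * med_cor(am))
  expect_gt(med_cor(int), med_cor(am_p))
})

test_that("activity beats raw TF expression when self-expression is off", {
  ds <- cached_dataset(1, tf_self_expression = FALSE)
  em <- normalize_log(filter_expression(as_expression_matrix(ds)))
  sig <- suppressMessages(single_cell_signatures(em))
  am <- suppressMessages(viper_matrix(sig, ds$truth$regulons))
  for (tf in rownames(am)) {
    act <- cor(am[tf, ], ds$truth$tf_activity[tf, colnames(am)],
               method = "spearman")
    expr <- abs(cor(em$layers$lognorm[tf, colnames(am)],
                    ds$truth$tf_activity[tf, colnames(am)],
                    method = "spearman"))
    expect_gt(act, expr)
  }
})
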