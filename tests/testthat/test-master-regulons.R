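# Branch differential signatures, regulon ranking, master selection and
# the expression/activity report.

test_that("rank-sum z matches wilcox.test and the separation closed form", {
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(60); grp <- rep(c(TRUE, FALSE), each = 30)
    x[grp] <- x[grp] + runif(1, 0, 2)
    z <- scregulon:::ranksum_z(x, grp)
    p_wil <- wilcox.test(x[grp], x[!grp], exact = FALSE,
                         correct = FALSE)$p.value
    expect_equal(2 * pnorm(-abs(z)), p_wil, tolerance = 1e-8)
  }
  # complete separation, n = 50 vs 50, no ties: z = 1250 / sqrt(2500*101/12)
  x <- c(seq_len(50) + 100, seq_len(50))
  grp <- rep(c(TRUE, FALSE), each = 50)
  expect_equal(scregulon:::ranksum_z(x, grp),
               1250 / sqrt(2500 * 101 / 12), tolerance = 1e-12)
})

test_that("branch signatures are antisymmetric and near zero for flat genes", {
  set.seed(2)
  ln <- matrix(rnorm(20 * 80), nrow = 20,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:80)))
  ln["g01", ] <- 5   # identical in both groups
  lab <- factor(rep(c("b1", "b2"), each = 40))
  s1 <- branch_signature(ln, lab, "b1")
  s2 <- branch_signature(ln, lab, "b2")
  expect_equal(unname(s1$z["g01"]), 0)
  expect_equal(s1$z, -s2$z, tolerance = 1e-12)
  expect_error(branch_signature(ln, lab, "b1", min_cells = 50),
               class = "scregulon_size_error")
})

test_that("a regulon built from the top branch genes ranks first", {
  set.seed(3)
  z <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  top <- names(sort(z, decreasing = TRUE))[1:20]
  regs <- regulon_set(list(
    HIT = data.frame(target = top, mode = 1, likelihood = 1),
    RND1 = data.frame(target = sample(names(z), 20), mode = 1, likelihood = 1),
    RND2 = data.frame(target = sample(names(z), 20),
                      mode = sample(c(-1, 1), 20, TRUE), likelihood = 1)))
  bsig <- structure(list(branch = "effector", z = z, n_branch = 50,
                         n_rest = 100), class = "branch_signature")
  rk <- rank_regulons(bsig, regs)
  expect_equal(rk$tf[1], "HIT")
  expect_gt(rk$nes[1], 0)
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(abs(rk$nes)) <= 1e-12))
})

test_that("random regulons on a permuted signature keep the FDR near nominal", {
  set.seed(1)
  z <- setNames(rnorm(500), sprintf("g%03d", 1:500))   # pure-null signature
  regs <- regulon_set(lapply(setNames(nm = sprintf("R%03d", 1:100)), function(nm) {
    sz <- sample(25:60, 1)
    data.frame(target = sample(names(z), sz),
               mode = sample(c(-1, 1), sz, TRUE), likelihood = 1)
  }))
  bsig <- structure(list(branch = "b", z = z, n_branch = 50, n_rest = 100),
                    class = "branch_signature")
  rk <- rank_regulons(bsig, regs)
  expect_lte(mean(rk$q < 0.05), 0.1)
})

test_that("master selection applies q, size and top-k rules", {
  rk <- structure(data.frame(
    tf = c("A", "B", "C", "D", "E"),
    nes = c(9, -8, 7, 6, 5),
    p = c(1e-18, 1e-15, 1e-12, 1e-9, 0.5),
    q = c(1e-17, 1e-14, 1e-11, 1e-8, 0.6),
    regulon_size = c(40, 30, 10, 28, 50),
    rank = 1:5), class = c("regulon_ranking", "data.frame"))
  expect_equal(select_masters(rk), c("A", "B", "D"))   # C too small, E not significant
  expect_equal(select_masters(rk, top_k = 2), c("A", "B"))
  rk$q <- 1
  expect_length(select_masters(rk), 0)
  expect_length(select_masters(rk[0, ]), 0)
})

test_that("BH adjustment matches the brute-force definition (property)", {
  for (s in 1:20) {
    set.seed(s)
    p <- runif(sample(5:50, 1))
    # brute force: sorted adjustment with cumulative minima from the right
    n <- length(p); o <- order(p)
    adj <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
    brute <- numeric(n); brute[o] <- adj
    expect_equal(p.adjust(p, "BH"), brute, tolerance = 1e-12)
  }
})

test_that("branch GRN export preserves modes and multiplicity", {
  regs <- regulon_set(list(
    A = data.frame(target = sprintf("t%02d", 1:25), mode = rep(c(1, -1), c(15, 10)),
                   likelihood = 1),
    B = data.frame(target = c(sprintf("t%02d", 1:5), sprintf("u%02d", 1:20)),
                   mode = 1, likelihood = 1)))
  z <- setNames(rnorm(60), c(sprintf("t%02d", 1:25), sprintf("u%02d", 1:20),
                             sprintf("v%02d", 1:15)))
  bsig <- structure(list(branch = "b", z = z, n_branch = 30, n_rest = 70),
                    class = "branch_signature")
  grn <- export_branch_grn(c("A", "B"), regs, bsig)
  expect_equal(nrow(grn), 50)
  expect_equal(sum(grn$tf == "A"), 25)
  expect_identical(grn$mode[grn$tf == "A"], regs$A$mode)
  shared <- grn[grn$target == "t01", ]
  expect_equal(nrow(shared), 2)                      # once per TF edge
  expect_equal(grn$target_z, unname(z[grn$target]))
})

test_that("expression/activity report has the right shapes and flat-case behavior", {
  ds <- cached_dataset(1)
  em <- normalize_log(filter_expression(as_expression_matrix(ds)))
  n <- length(em$cell_ids)
  act <- structure(matrix(0, 1, n, dimnames = list("ZEB2", em$cell_ids)),
                   class = c("activity_matrix", "matrix"))
  branches <- factor(rep(c("x", "y"), length.out = n))
  tissues <- ds$annotation$tissue[match(em$cell_ids, ds$annotation$cell_id)]
  rep_out <- expression_vs_activity_report("ZEB2", em, act, branches, tissues,
                                           cytotox_score = rnorm(n))
  expect_equal(nrow(rep_out$by_tissue), 1 * length(unique(tissues)))
  expect_equal(nrow(rep_out$by_branch), 2)
  # constant activity: identical means across branches
  expect_equal(rep_out$by_branch$mean_activity, c(0, 0))
  expect_equal(nrow(rep_out$expression_correlation), 3)
})

test_that("the planted effector activity peaks in the effector branch", {
  res <- cached_pipeline(1)
  rep_b <- res$report$by_branch
  zeb <- rep_b[rep_b$tf == "ZEB2", ]
  expect_equal(zeb$branch[which.max(zeb$mean_activity)], "effector")
})
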