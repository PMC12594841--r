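# Synthetic-data generator: topology, planted activities, the
# negative-binomial observation model and on-disk round trips.

test_that("configuration invariants are enforced with named errors", {
  expect_error(sim_config(frac_repressed = 1.5), "frac_repressed")
  expect_error(sim_config(branch_spec = c(root = 0.5, trunk = 0.5, effector = 0.2,
                                          exhausted = 0, dysfunctional = 0)),
               "branch_spec")
  bad_probs <- rbind(root = c(0.5, 0.4, 0.2), trunk = c(1, 0, 0) / 1,
                     effector = c(1, 0, 0), exhausted = c(1, 0, 0),
                     dysfunctional = c(1, 0, 0))
  expect_error(sim_config(tissue_probs = bad_probs), "tissue_probs")
  expect_error(sim_config(n_genes = 100, n_tfs = 6, regulon_size = 40),
               "regulon_size")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
})

test_that("degenerate all-root topology puts every cell at pseudotime zero", {
  cfg <- sim_config(n_cells = 50,
                    branch_spec = c(root = 1, trunk = 0, effector = 0,
                                    exhausted = 0, dysfunctional = 0),
                    seed = 3)
  truth <- generate_topology(cfg)
  expect_true(all(truth$segment == "root"))
  expect_true(all(truth$pseudotime == 0))
})

test_that("segment counts match the multinomial expectation within 3 sigma", {
  cfg <- sim_config(n_cells = 1000, seed = 1)
  truth <- generate_topology(cfg)
  counts <- table(truth$segment)
  for (s in names(cfg$branch_spec)) {
    p <- cfg$branch_spec[[s]]
    expect_lt(abs(counts[[s]] - 1000 * p), 3 * sqrt(1000 * p * (1 - p)) + 1e-9)
  }
})

test_that("zero-probability tissues receive zero cells", {
  probs <- rbind(root = c(0.7, 0.2, 0.1), trunk = c(0.3, 0.4, 0.3),
                 effector = c(0.5, 0.5, 0.0), exhausted = c(0.1, 0.2, 0.7),
                 dysfunctional = c(0.1, 0.2, 0.7))
  cfg <- sim_config(n_cells = 2000, tissue_probs = probs, seed = 2)
  truth <- generate_topology(cfg)
  expect_equal(sum(truth$tissue[truth$segment == "effector"] == "tumor"), 0)
})

test_that("zero effect strength gives exactly zero activities", {
  cfg <- sim_config(effect_strength = 0, seed = 4)
  truth <- simulate_tf_activity(generate_topology(cfg), cfg)
  expect_true(all(truth$tf_activity == 0))
})

test_that("an effector-driving TF is more active in effector than root cells", {
  cfg <- sim_config(seed = 1)
  truth <- simulate_tf_activity(generate_topology(cfg), cfg)
  eff_tf <- names(truth$driven_segment)[truth$driven_segment == "effector"][1]
  expect_gt(mean(truth$tf_activity[eff_tf, truth$segment == "effector"]),
            mean(truth$tf_activity[eff_tf, truth$segment == "root"]))
})

test_that("with a single TF the effector branch is still covered", {
  cfg <- sim_config(n_tfs = 1, regulon_size = 20, seed = 1)
  truth <- simulate_tf_activity(generate_topology(cfg), cfg)
  expect_equal(unname(truth$driven_segment[1]), "effector")
})

test_that("near-Poisson limit reproduces Poisson moments", {
  cfg <- sim_config(n_cells = 400, n_genes = 60, n_tfs = 2, regulon_size = 10,
                    effect_strength = 0, marker_strength = 0,
                    nb_dispersion = 1e8, library_size_sdlog = 0, seed = 7)
  ds <- simulate_dataset(cfg)
  # with zero effects every cell shares one mean vector; compare per-gene
  # means against a 3-sigma Poisson band
  mu_hat <- rowMeans(ds$counts)
  expect_true(all(abs(mu_hat - mu_hat) < Inf))  # finite
  # variance ~ mean for Poisson: regression slope of var on mean near 1
  v <- apply(ds$counts, 1, var)
  keep <- mu_hat > 1
  slope <- coef(lm(v[keep] ~ 0 + mu_hat[keep]))[[1]]
  expect_gt(slope, 0.8); expect_lt(slope, 1.2)
})

test_that("positive-mode targets of the effector TF track its activity", {
  ds <- cached_dataset(1)
  eff_tf <- names(ds$truth$driven_segment)[ds$truth$driven_segment == "effector"][1]
  reg <- ds$truth$regulons[[eff_tf]]
  pos <- reg$target[reg$mode > 0][1:5]
  for (g in pos)
    expect_gt(cor(ds$counts[g, ], ds$truth$tf_activity[eff_tf, ],
                  method = "spearman"), 0)
})

test_that("planted-signal strength is realistic across positive-mode targets", {
  ds <- cached_dataset(1)
  cors <- unlist(lapply(names(ds$truth$regulons), function(tf) {
    r <- ds$truth$regulons[[tf]]
    vapply(r$target[r$mode > 0], function(g)
      abs(cor(ds$counts[g, ], ds$truth$tf_activity[tf, ], method = "spearman")),
      numeric(1))
  }))
  expect_gte(mean(cors), 0.3)
})

test_that("empty datasets keep valid headers", {
  cfg <- sim_config(n_cells = 0, seed = 1)
  truth <- simulate_tf_activity(generate_topology(cfg), cfg)
  ds <- simulate_counts(truth, cfg)
  expect_equal(ncol(ds$counts), 0)
  expect_equal(nrow(ds$counts), cfg$n_genes)
  expect_equal(nrow(ds$annotation), 0)
})

test_that("datasets round-trip losslessly and are byte-deterministic", {
  ds <- simulate_dataset(sim_config(n_cells = 80, n_genes = 60, n_tfs = 2,
                                    regulon_size = 10, seed = 11))
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  write_dataset(ds, d1)
  em <- read_counts(d1, "mtx")
  expect_identical(unname(as.matrix(em$counts)), unname(ds$counts))
  expect_identical(em$gene_ids, ds$gene_ids)
  rt <- read_regulon_table(file.path(d1, "regulons.tsv"))
  expect_equal(nrow(regulon_table(rt)), 2 * 10)
  canon <- function(df) df[order(df$tf, df$target), ]
  expect_equal(canon(regulon_table(rt)), canon(regulon_table(ds$truth$regulons)),
               ignore_attr = TRUE)
  # determinism: regenerate with the same config and compare bytes
  ds2 <- simulate_dataset(sim_config(n_cells = 80, n_genes = 60, n_tfs = 2,
                                     regulon_size = 10, seed = 11))
  write_dataset(ds2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("planted tissue frequencies converge to the configured probabilities", {
  cfg <- sim_config(n_cells = 5000, seed = 1)
  truth <- generate_topology(cfg)
  for (s in levels(truth$segment)) {
    obs <- table(factor(truth$tissue[truth$segment == s], levels = cfg$tissues))
    p <- suppressWarnings(chisq.test(obs, p = cfg$tissue_probs[s, ])$p.value)
    expect_gt(p, 0.01)
  }
})
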