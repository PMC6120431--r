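test_that("simulator is deterministic and honours the configured design", {
  cfg <- sim_config(n_genes = 100, seed = 11)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  # study-shaped default: 2 sites x 2 tides x 3 times x 3 reps minus 1 drop
  expect_equal(nrow(a$design), 35)
  expect_false("LT_I_0h_r2" %in% a$design$sample_id)
  expect_equal(ncol(a$counts) - 1, 35)
})

test_that("effect-free config varies expected counts only via library size", {
  cfg <- sim_config(n_genes = 50, fraction_divergent = 0, fraction_plastic = 0,
                    seed = 2)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$divergence_log2 == 0))
  expect_true(all(sim$truth$plasticity_log2 == 0))
  expect_true(all(!sim$truth$is_divergent))
  # normalized column means should be flat across samples up to noise
  m <- as.matrix(sim$counts[, -1])
  norm_means <- colMeans(sweep(m, 2, sim$sample_truth$size_factor, "/"))
  expect_lt(max(abs(norm_means / mean(norm_means) - 1)), 0.25)
})

test_that("planted effect correlation is achieved over doubly-affected genes", {
  for (rho in c(-0.5, 0, 0.71, 0.9)) {
    cfg <- sim_config(n_genes = 2500, fraction_divergent = 0.8,
                      fraction_plastic = 0.8, rho_true = rho, seed = 21)
    sim <- simulate_counts(cfg)
    tr <- sim$truth
    both <- tr$is_divergent & tr$is_plastic
    expect_gte(sum(both), 1000)
    expect_lt(abs(cor(tr$divergence_log2[both], tr$plasticity_log2[both]) - rho),
              0.05)
  }
  # rho_true = 1 with everything affected: near-perfect linear relation
  cfg1 <- sim_config(n_genes = 2000, fraction_divergent = 1, fraction_plastic = 1,
                     rho_true = 1, seed = 5)
  tr1 <- simulate_counts(cfg1)$truth
  expect_gte(cor(tr1$divergence_log2, tr1$plasticity_log2), 0.95)
})

test_that("configured nonzero fractions are met up to rounding", {
  cfg <- sim_config(n_genes = 1000, fraction_divergent = 0.13,
                    fraction_plastic = 0.27, seed = 9)
  tr <- simulate_counts(cfg)$truth
  expect_equal(sum(tr$is_divergent), 130)
  expect_equal(sum(tr$is_plastic), 270)
  expect_true(all(tr$dispersion > 0))
  expect_true(all(tr$divergence_log2[!tr$is_divergent] == 0))
})

test_that("counts match NB moments for spot-checked genes", {
  # 200 replicate draws of the same config; compare empirical mean/variance
  # of 20 genes in one sample against NB(mean, alpha) within 3 SE
  cfg <- sim_config(n_genes = 500, sites = "BYQ", dropped_samples = character(),
                    fraction_divergent = 0, fraction_plastic = 0, seed = 33)
  base <- simulate_counts(cfg)
  genes <- seq(10, 200, by = 10)
  sample_j <- 4
  draws <- vapply(seq_len(200), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- 10000L + r
    as.matrix(simulate_counts(cfg_r)$counts[genes, sample_j + 1])[, 1]
  }, numeric(length(genes)))
  # truth depends only on the seed, so recompute per draw; instead check
  # against per-draw expected moments averaged over draws via z-scores of
  # the mean under each draw's own truth
  zs <- vapply(seq_len(200), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- 10000L + r
    sim <- simulate_counts(cfg_r)
    mu <- sim$sample_truth$size_factor[sample_j] *
      2^sim$truth$baseline_log2[genes]
    v <- mu + sim$truth$dispersion[genes] * mu^2
    (draws[, r] - mu) / sqrt(v)
  }, numeric(length(genes)))
  # per gene, mean of 200 standardized residuals ~ N(0, 1/200)
  zbar <- rowMeans(zs)
  expect_true(all(abs(zbar) < 3 / sqrt(200)))
})

test_that("degenerate configs are rejected", {
  expect_error(sim_config(n_genes = 0, seed = 1), "n_genes")
  expect_error(sim_config(times = c(6, 24), seed = 1), "baseline")
  expect_error(sim_config(replicates = 1, seed = 1), "replicates|2 replicates")
  expect_error(sim_config(rho_true = 1.2, seed = 1), "rho_true")
  expect_error(sim_config(), "seed")
})

test_that("null generator plants no effects", {
  sim <- simulate_null_shared_baseline(sim_config(n_genes = 40, seed = 8))
  expect_true(all(sim$truth$divergence_log2 == 0))
  expect_true(all(sim$truth$plasticity_log2 == 0))
})
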