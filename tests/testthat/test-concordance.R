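test_that("concordance fraction counts strict same-sign products", {
  out <- concordance_fraction(c(1, -2, 3), c(0.5, -1, -0.2))
  expect_equal(out$np, 2)
  expect_equal(out$nt, 3)
  expect_equal(out$percent, 66.67)
  # ties (product exactly 0) stay in Nt but not in Np
  tie <- concordance_fraction(c(1, 0, -1), c(2, 5, 0))
  expect_equal(tie$np, 1)
  expect_equal(tie$nt, 3)
  expect_error(concordance_fraction(numeric(0), numeric(0)), "at least one")
})

test_that("reported percents use half-up rounding at 2 decimals", {
  # representative Np/Nt pairs and their published-style percents
  cases <- list(
    c(65, 85, 76.47), c(61, 74, 82.43), c(64, 86, 74.42), c(53, 74, 71.62),
    c(221, 362, 61.05), c(220, 315, 69.84), c(189, 361, 52.35),
    c(153, 296, 51.69), c(29, 32, 90.63), c(24, 26, 92.31),
    c(26, 32, 81.25), c(17, 25, 68.00)
  )
  for (cs in cases) {
    E <- c(rep(1, cs[1]), rep(-1, cs[2] - cs[1]))
    D <- rep(1, cs[2])
    expect_equal(concordance_fraction(E, D)$percent, cs[3])
  }
})

test_that("spearman_rho equals the brute-force mid-rank oracle", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)
  set.seed(9)
  for (r in 1:100) {
    # vectors of 20 with heavy ties
    x <- sample(1:6, 20, replace = TRUE) + rnorm(20, 0, 0.01 * (r %% 2))
    y <- sample(1:6, 20, replace = TRUE)
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-12)
  }
  expect_warning(z <- spearman_rho(rep(1, 5), 1:5), "zero rank variance")
  expect_true(is.nan(z))
})

test_that("divergence and plasticity vectors recover planted group means", {
  d <- make_axis_data(n_genes = 50, offset = 0, delta = 0, noise = 0, seed = 3)
  # identical expression everywhere: all vectors zero
  flat <- expr_tibble(matrix(5, 50, nrow(d$design),
                             dimnames = list(d$expr$gene_id, d$design$sample_id)))
  E <- divergence_vector(flat, d$design, d$expr$gene_id, "X")
  D <- plasticity_vector(flat, d$design, d$expr$gene_id, "X", 6)
  expect_true(all(E == 0) && all(D == 0))

  # planted offsets appear with the right sign and size
  d2 <- make_axis_data(n_genes = 40, offset = 2, delta = 1.5, noise = 0, seed = 4)
  E2 <- divergence_vector(d2$expr, d2$design, d2$expr$gene_id, "X")
  D2 <- plasticity_vector(d2$expr, d2$design, d2$expr$gene_id, "X", 6, tide = "S")
  expect_equal(unname(E2), 2 * d2$v, tolerance = 1e-10)
  expect_equal(unname(D2), 1.5 * d2$v, tolerance = 1e-10)
})

test_that("concordance statistics are invariant to joint sign flips", {
  set.seed(11)
  E <- rnorm(40)
  D <- rnorm(40)
  expect_equal(concordance_fraction(E, D), concordance_fraction(-E, -D))
  expect_equal(spearman_rho(E, D), spearman_rho(-E, -D), tolerance = 1e-12)
})

test_that("permutation test gives minimal p for separable planted signal", {
  # strong perfectly concordant signal: observed rho beats every permutation
  d <- make_axis_data(n_genes = 200, offset = 0, delta = 0, noise = 0.05,
                      seed = 21)
  m <- as.matrix(d$expr[, -1])
  rownames(m) <- d$expr$gene_id
  set.seed(22)
  eff <- rnorm(200, 0, 2)
  for (j in seq_len(nrow(d$design))) {
    row <- d$design[j, ]
    m[, j] <- m[, j] + (row$tide == "I") * eff + (row$time_h > 0) * eff
  }
  expr <- expr_tibble(m)
  pt <- permutation_test(expr, d$design, d$expr$gene_id, "X", 6, B = 1000,
                         seed = 5)
  # role-swapping permutations can reproduce a strong single-direction
  # signal's |rho|, so the attainable p is small but not 1/(B+1)
  expect_lt(pt$summary$p_perm, 0.05)
  expect_gt(pt$summary$rho, 0.9)
  expect_error(permutation_test(expr, d$design, d$expr$gene_id, "X", 6, B = 0),
               "B must be")
})

test_that("permutation p lies in [1/(B+1), 1] and observed stat ignores B", {
  d <- make_axis_data(n_genes = 60, noise = 0.3, seed = 31)
  p1 <- permutation_test(d$expr, d$design, d$expr$gene_id, "X", 6, B = 50,
                         seed = 1)
  p2 <- permutation_test(d$expr, d$design, d$expr$gene_id, "X", 6, B = 100,
                         seed = 2)
  expect_equal(p1$summary$rho, p2$summary$rho)
  for (p in c(p1$summary$p_perm, p2$summary$p_perm)) {
    expect_gte(p, 1 / (p2$summary$n_perm + 1))
    expect_lte(p, 1)
  }
})

test_that("shared-baseline estimator is biased upward on pure noise, split is not", {
  cfg <- sim_config(n_genes = 5000, seed = 5, dropped_samples = character())
  sim <- simulate_null_shared_baseline(cfg)
  f <- filter_low_expression(sim$counts)
  expr <- rlog_transform(f)
  rho_shared <- divergence_plasticity_rho(expr, sim$design, f$gene_id, "BYQ", 6,
                                          method = "shared")
  rho_split <- divergence_plasticity_rho(expr, sim$design, f$gene_id, "BYQ", 6,
                                         method = "split")
  expect_gt(rho_shared, 0.40)
  expect_lt(rho_shared, 0.60)
  expect_gt(rho_split, -0.10)
  expect_lt(rho_split, 0.10)

  rep_tbl <- shared_baseline_bias_report(expr, sim$design, f$gene_id, "BYQ")
  expect_equal(nrow(rep_tbl), 2)
  expect_true(all(rep_tbl$split_available))
  expect_true(all(rep_tbl$rho_shared > rep_tbl$rho_split))
})

test_that("zero-noise deterministic input makes both estimators agree", {
  d <- make_axis_data(n_genes = 60, offset = 2, delta = 1, noise = 0, seed = 2)
  shared <- divergence_plasticity_rho(d$expr, d$design, d$expr$gene_id, "X", 6,
                                      method = "shared")
  split <- divergence_plasticity_rho(d$expr, d$design, d$expr$gene_id, "X", 6,
                                     method = "split")
  expect_equal(shared, split, tolerance = 1e-10)
})

test_that("split-replicate estimator is closer to truth when noise dominates", {
  # pure-noise regime: the shared baseline inflates the shared estimator
  # toward 0.5 on every run, while the split estimator stays near the true 0
  hits <- 0
  n_runs <- 20
  for (r in seq_len(n_runs)) {
    cfg <- sim_config(n_genes = 800, seed = 400 + r,
                      dropped_samples = character())
    sim <- simulate_null_shared_baseline(cfg)
    f <- filter_low_expression(sim$counts)
    expr <- rlog_transform(f)
    sh <- divergence_plasticity_rho(expr, sim$design, f$gene_id, "BYQ", 6, "S",
                                    "shared")
    sp <- divergence_plasticity_rho(expr, sim$design, f$gene_id, "BYQ", 6, "S",
                                    "split")
    if (abs(sp) < abs(sh)) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.8)
})
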