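test_that("discriminant axis aligns with a planted separation direction", {
  d <- make_axis_data(n_genes = 500, replicates = 10, offset = 3, delta = 0,
                      noise = 0.1, seed = 42, times = 0)
  fit <- fit_dapc(d$expr, d$design)
  w <- fit$loadings %*% fit$axis
  expect_gte(abs(sum(w * d$v)), 0.9)
  expect_equal(sqrt(sum(fit$axis^2)), 1, tolerance = 1e-10)
  expect_lte(fit$k, nrow(d$design) - 2)
})

test_that("identical group means yield near-zero separation, not an error", {
  d <- make_axis_data(n_genes = 100, offset = 0, delta = 0, noise = 0.2,
                      seed = 13)
  fit <- fit_dapc(d$expr, d$design)
  sc <- fit$scores
  base <- sc[sc$time_h == 0, ]
  sep <- abs(mean(base$score[base$group == "I"]) -
               mean(base$score[base$group == "S"]))
  noise_sd <- sd(base$score)
  expect_lt(sep, 3 * noise_sd)
})

test_that("axis and scores are invariant to gene order and per-gene constants", {
  d <- make_axis_data(n_genes = 120, seed = 77, noise = 0.1)
  fit1 <- fit_dapc(d$expr, d$design)
  # permute genes
  perm <- d$expr[sample(nrow(d$expr)), ]
  fit2 <- fit_dapc(perm, d$design)
  expect_equal(fit1$scores$score, fit2$scores$score, tolerance = 1e-8)
  # add a constant to one gene's values everywhere (absorbed by centering)
  shifted <- d$expr
  shifted[5, -1] <- shifted[5, -1] + 100
  fit3 <- fit_dapc(shifted, d$design)
  expect_equal(fit1$scores$score, fit3$scores$score, tolerance = 1e-8)
})

test_that("with full variance retained and no shrinkage DAPC matches direct LDA", {
  # enough baseline samples that the within scatter is well conditioned
  d <- make_axis_data(n_genes = 8, replicates = 12, offset = 2, delta = 0,
                      noise = 0.5, seed = 10, times = 0)
  fit <- fit_dapc(d$expr, d$design, var_retained = 1.0, w_shrink = 0)
  m <- t(as.matrix(d$expr[, -1]))
  ref <- MASS::lda(m, grouping = d$design$tide)
  proj_ours <- fit$scores$score
  proj_ref <- as.numeric(scale(m, center = TRUE, scale = FALSE) %*% ref$scaling)
  # same axis up to sign and scale
  expect_gte(abs(cor(proj_ours, proj_ref)), 1 - 1e-8)
})

test_that("planted axis displacement is recovered within 10%", {
  errs <- vapply(1:10, function(r) {
    d <- make_axis_data(n_genes = 500, offset = 3, delta = 2, noise = 0.05,
                        seed = 500 + r)
    fit <- fit_dapc(d$expr, d$design)
    abs(shift_magnitude(fit, "I", 6)$magnitude - 2) / 2
  }, numeric(1))
  expect_lte(mean(errs), 0.10)

  # identical scores at t and 0 h give zero shift; missing cells error
  d <- make_axis_data(n_genes = 50, seed = 3)
  fit <- fit_dapc(d$expr, d$design)
  fit$scores$score <- rep(1, nrow(fit$scores))
  expect_equal(shift_magnitude(fit, "I", 6)$shift, 0)
  expect_error(shift_magnitude(fit, "I", 12), "no samples")
})

test_that("population ordering of planted displacements is preserved", {
  hits <- vapply(1:20, function(r) {
    d <- make_axis_data(n_genes = 400, offset = 3, delta = 2, delta_S = 0.7,
                        noise = 0.1, seed = 900 + r)
    fit <- fit_dapc(d$expr, d$design)
    shift_magnitude(fit, "I", 6)$magnitude >
      shift_magnitude(fit, "S", 6)$magnitude
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("mcmc inference is reproducible and matches least squares when noise is tiny", {
  sc <- make_scores(2, 1, noise = 0.01, rep_sd = 0.01, seed = 5)
  a <- mcmc_shift_inference(sc, n_retained = 600, burnin = 200, thin = 2,
                            seed = 9)
  b <- mcmc_shift_inference(sc, n_retained = 600, burnin = 200, thin = 2,
                            seed = 9)
  expect_identical(a$draws, b$draws)
  expect_equal(nrow(a$draws), 600)

  ls_fit <- stats::lm(score ~ group * factor(time_h), data = sc)
  ls_int <- stats::coef(ls_fit)[["groupS:factor(time_h)6"]]
  post <- a$contrasts$estimate[a$contrasts$time_h == 6]
  expect_equal(post, ls_int, tolerance = 0.02)
  # credible interval contains the point estimate
  expect_true(all(a$contrasts$conf.low <= a$contrasts$estimate &
                    a$contrasts$estimate <= a$contrasts$conf.high))
  expect_true(all(a$contrasts$p_mcmc >= 1 / 600 & a$contrasts$p_mcmc <= 1))
})

test_that("a large planted shift difference is detected", {
  sc <- make_scores(3, 1, noise = 0.2, rep_sd = 0.2, seed = 41)
  inf <- mcmc_shift_inference(sc, n_retained = 1400, burnin = 300, thin = 2,
                              seed = 42)
  expect_lt(inf$contrasts$p_mcmc[inf$contrasts$time_h == 6], 0.05)
  expect_true(all(inf$contrasts$converged))
})
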