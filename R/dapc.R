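#' Discriminant axis of principal components for expression shifts
#'
#' Builds the "unstressed ruler": genes are centered, samples are projected
#' onto principal components, the smallest number of PCs reaching
#' `var_retained` of the variance is kept (capped at the number of
#' unstressed samples minus the number of groups, the classic DAPC overfit
#' guard), and a Fisher linear discriminant between the two populations is
#' fit on the *unstressed* (baseline-time) samples only. All samples —
#' stressed and unstressed — are then scored on that axis, so stress-induced
#' shifts are measured on the scale that separates the populations at rest.
#'
#' @param expr Wide expression tibble (genes x samples).
#' @param design Validated design tibble.
#' @param groups Name of the design column holding the population labels
#'   (default `"tide"`); exactly two groups are supported.
#' @param site Optional site label to restrict the analysis to one site.
#' @param var_retained Fraction of variance the retained PCs must reach.
#' @param baseline_time Unstressed time defining the discriminant samples.
#' @param w_shrink Shrinkage of the within-group scatter toward isotropy
#'   (`(1 - w_shrink) * W + w_shrink * (tr(W)/k) * I`, regularized LDA).
#'   With the design's few unstressed samples the raw scatter is nearly
#'   singular and unshrunk Fisher axes are unstable; default 0.5.
#' @param ridge Additional relative ridge guarding against an exactly
#'   singular scatter.
#' @return Object of class `tidal_dapc`: PC loadings, variance fractions,
#'   number of retained PCs, unit-norm discriminant axis (in PC space), and
#'   a `scores` tibble (sample_id, group, time_h, score).
#' @export
fit_dapc <- function(expr, design, groups = "tide", site = NULL,
                     var_retained = 0.80, baseline_time = 0, w_shrink = 0.5,
                     ridge = 1e-6) {
  design <- validate_design(design)
  if (!is.null(site)) {
    keep <- design$site == site
    m <- align_to_design(expr, design, "expression")[, keep, drop = FALSE]
    design <- design[keep, , drop = FALSE]
  } else {
    m <- align_to_design(expr, design, "expression")
  }
  if (var_retained <= 0 || var_retained > 1) {
    abort("var_retained must lie in (0, 1]")
  }
  g <- design[[groups]]
  if (is.null(g)) abort(sprintf("design has no column '%s'", groups))
  base_idx <- design$time_h == baseline_time
  glev <- unique(g[base_idx])
  if (length(glev) != 2) {
    abort("fit_dapc supports exactly 2 groups among the unstressed samples")
  }
  n0 <- sum(base_idx)
  if (n0 < length(glev) + 1) abort("too few unstressed samples")

  x <- t(m)                       # samples x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(x, center = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  k_var <- which(cumsum(var_frac) >= var_retained)[1]
  k_cap <- max(1, n0 - length(glev))
  k <- min(k_var, k_cap, sum(pc$sdev > 1e-10))
  scores_pc <- pc$x[, seq_len(k), drop = FALSE]

  s0 <- scores_pc[base_idx, , drop = FALSE]
  g0 <- g[base_idx]
  m1 <- colMeans(s0[g0 == glev[1], , drop = FALSE])
  m2 <- colMeans(s0[g0 == glev[2], , drop = FALSE])
  W <- matrix(0, k, k)
  for (lev in glev) {
    xi <- sweep(s0[g0 == lev, , drop = FALSE], 2,
                colMeans(s0[g0 == lev, , drop = FALSE]))
    W <- W + crossprod(xi)
  }
  tr <- sum(diag(W))
  if (tr <= 0) tr <- 1
  Wr <- (1 - w_shrink) * W + (w_shrink * tr / k + ridge * tr) * diag(k)
  a <- solve(Wr, m1 - m2)
  a <- a / sqrt(sum(a^2))
  # Orient the axis so the first group level scores higher at baseline.
  if (sum(a * (m1 - m2)) < 0) a <- -a

  structure(
    list(
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      var_frac = var_frac,
      k = k,
      axis = a,
      group_levels = glev,
      groups_col = groups,
      baseline_time = baseline_time,
      scores = tibble(
        sample_id = design$sample_id,
        group = g,
        time_h = design$time_h,
        replicate = design$replicate,
        score = as.numeric(scores_pc %*% a)
      )
    ),
    class = "tidal_dapc"
  )
}

#' @export
print.tidal_dapc <- function(x, ...) {
  cat(sprintf(
    "DAPC model: %d PCs retained (%.1f%% variance), axis %s vs %s at %g h\n",
    x$k, 100 * sum(x$var_frac[seq_len(x$k)]), x$group_levels[1],
    x$group_levels[2], x$baseline_time
  ))
  invisible(x)
}

#' @export
tidy.tidal_dapc <- function(x, ...) {
  x$scores
}

#' @export
glance.tidal_dapc <- function(x, ...) {
  tibble(
    n_pcs = x$k,
    var_retained = sum(x$var_frac[seq_len(x$k)]),
    n_samples = nrow(x$scores)
  )
}

#' Expression shift along the unstressed discriminant axis
#'
#' The shift of a population at stressed time t is the difference between its
#' mean axis score at t and at the unstressed baseline; its magnitude is the
#' genome-wide expression-plasticity measure.
#'
#' @param model A `tidal_dapc` model.
#' @param population Group label (e.g. `"I"` or `"S"`).
#' @param time Stressed time (hours).
#' @return One-row tibble: `population`, `time_h`, `shift` (signed),
#'   `magnitude`.
#' @export
shift_magnitude <- function(model, population, time) {
  sc <- model$scores
  at_t <- sc$score[sc$group == population & sc$time_h == time]
  at_0 <- sc$score[sc$group == population & sc$time_h == model$baseline_time]
  if (length(at_t) == 0 || length(at_0) == 0) {
    abort(sprintf("no samples for population %s at %g h and/or baseline",
                  population, time))
  }
  m <- mean(at_t) - mean(at_0)
  tibble(population = population, time_h = time, shift = m, magnitude = abs(m))
}

#' Bayesian linear mixed model for axis-score shifts
#'
#' Fits `score ~ population * time + (1 | replicate)` to the per-sample axis
#' scores by a conjugate Gibbs sampler: flat-ish normal priors on the fixed
#' effects (`N(0, 100 * var(score))`), inverse-gamma(0.001, 0.001) priors on
#' the random-effect and residual variances. After `burnin` iterations and
#' thinning by `thin`, exactly `n_retained` posterior draws are kept. For
#' each stressed time the population contrast "shift of population 2 minus
#' shift of population 1" (the population x time interaction) is summarized
#' by its posterior mean, a 95% credible interval, and a two-sided posterior
#' tail probability `P = 2 * min(Pr(c > 0), Pr(c < 0))` (floored at
#' `1 / n_retained`). Convergence is monitored with a split-half R-hat on
#' each contrast; values above 1.1 trigger a warning and a flag.
#'
#' @param scores Tibble with columns `score`, `group`, `time_h`, `replicate`
#'   (as produced by [fit_dapc()], `tidy()` on the model).
#' @param baseline_time Unstressed time level.
#' @param n_retained Number of posterior draws to keep (default 2800).
#' @param burnin,thin Gibbs burn-in and thinning.
#' @param seed RNG seed.
#' @return Object of class `shift_inference`: `contrasts` tibble
#'   (`time_h`, `estimate`, `conf.low`, `conf.high`, `p_mcmc`, `rhat`,
#'   `converged`), `shifts` tibble of per-population point estimates, the
#'   retained `draws` matrix and the model frame.
#' @export
mcmc_shift_inference <- function(scores, baseline_time = 0,
                                 n_retained = 2800, burnin = 500, thin = 5,
                                 seed = 1) {
  need <- c("score", "group", "time_h", "replicate")
  missing <- setdiff(need, names(scores))
  if (length(missing) > 0) {
    abort(sprintf("scores is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (n_retained < 10) abort("n_retained must be >= 10")
  y <- scores$score
  pop <- factor(scores$group)
  tim <- factor(scores$time_h,
                levels = sort(unique(scores$time_h)))
  if (nlevels(pop) != 2) abort("exactly 2 populations are required")
  rep_f <- factor(scores$replicate)
  X <- model.matrix(~ pop * tim)
  Z <- model.matrix(~ rep_f - 1)
  n <- length(y); p <- ncol(X); q <- ncol(Z)

  set.seed(seed)
  n_iter <- burnin + n_retained * thin
  prior_var_beta <- 100 * max(var(y), 1e-6)
  a0 <- b0 <- 1e-3

  beta <- rep(0, p); u <- rep(0, q)
  sigma2_e <- max(var(y), 1e-6); sigma2_u <- sigma2_e / 2
  XtX <- crossprod(X); ZtZ_diag <- colSums(Z^2)
  draws <- matrix(NA_real_, n_retained, p,
                  dimnames = list(NULL, colnames(X)))
  kept <- 0
  for (it in seq_len(n_iter)) {
    # beta | rest
    prec <- XtX / sigma2_e + diag(1 / prior_var_beta, p)
    resid_u <- y - as.numeric(Z %*% u)
    mu_b <- solve(prec, crossprod(X, resid_u) / sigma2_e)
    beta <- as.numeric(mu_b + backsolve(chol(prec), rnorm(p)))
    # u | rest
    resid_b <- y - as.numeric(X %*% beta)
    prec_u <- ZtZ_diag / sigma2_e + 1 / sigma2_u
    mu_u <- (crossprod(Z, resid_b) / sigma2_e) / prec_u
    u <- as.numeric(mu_u) + rnorm(q) / sqrt(prec_u)
    # variances | rest
    resid <- resid_b - as.numeric(Z %*% u)
    sigma2_e <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(resid^2) / 2)
    sigma2_u <- 1 / stats::rgamma(1, a0 + q / 2, b0 + sum(u^2) / 2)
    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1
      draws[kept, ] <- beta
    }
  }

  stressed <- setdiff(levels(tim), as.character(baseline_time))
  pop2 <- levels(pop)[2]
  contrasts <- purrr::map_dfr(stressed, function(tl) {
    cn <- sprintf("pop%s:tim%s", pop2, tl)
    if (!cn %in% colnames(draws)) {
      abort(sprintf("contrast column %s not found", cn))
    }
    cs <- draws[, cn]
    half <- floor(length(cs) / 2)
    rhat <- split_rhat(cs[seq_len(half)], cs[(half + 1):(2 * half)])
    tail_hi <- mean(cs > 0)
    p2 <- max(2 * min(tail_hi, 1 - tail_hi), 1 / n_retained)
    tibble(
      time_h = as.numeric(tl),
      estimate = mean(cs),
      conf.low = unname(quantile(cs, 0.025)),
      conf.high = unname(quantile(cs, 0.975)),
      p_mcmc = min(p2, 1),
      rhat = rhat,
      converged = rhat <= 1.1
    )
  })
  if (any(!contrasts$converged)) {
    warn("mcmc_shift_inference: split R-hat > 1.1 on a contrast; inspect chains")
  }

  shifts <- purrr::map_dfr(levels(pop), function(pl) {
    purrr::map_dfr(as.numeric(stressed), function(t) {
      at_t <- y[pop == pl & scores$time_h == t]
      at_0 <- y[pop == pl & scores$time_h == baseline_time]
      tibble(population = pl, time_h = t,
             shift = mean(at_t) - mean(at_0),
             magnitude = abs(mean(at_t) - mean(at_0)))
    })
  })

  structure(
    list(contrasts = contrasts, shifts = shifts, draws = draws,
         populations = levels(pop), n_retained = n_retained),
    class = "shift_inference"
  )
}

split_rhat <- function(a, b) {
  mchain <- c(mean(a), mean(b))
  wvar <- mean(c(var(a), var(b)))
  if (wvar <= 0) return(1)
  n <- length(a)
  bvar <- n * var(mchain)
  sqrt(((n - 1) / n * wvar + bvar / n) / wvar)
}

#' @export
print.shift_inference <- function(x, ...) {
  cat(sprintf("Axis-shift inference (%d retained MCMC draws)\n", x$n_retained))
  print(x$contrasts)
  invisible(x)
}

#' @export
tidy.shift_inference <- function(x, ...) {
  x$contrasts
}

#' @export
glance.shift_inference <- function(x, ...) {
  tibble(
    n_retained = x$n_retained,
    min_p_mcmc = min(x$contrasts$p_mcmc),
    all_converged = all(x$contrasts$converged)
  )
}
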