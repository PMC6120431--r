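#' Remove low-expression genes
#'
#' A gene is removed when it has fewer than `min_count` counts in more than
#' `max_fraction_below` of the samples (both inequalities strict). With the
#' defaults this is the "fewer than 10 counts in more than 90% of samples"
#' rule; a gene with exactly `min_count` counts everywhere is kept, and a
#' fraction-below of exactly `max_fraction_below` is kept.
#'
#' @param counts Wide counts tibble.
#' @param min_count Count threshold (strict: counts < `min_count` are "low").
#' @param max_fraction_below Maximum tolerated fraction of low samples
#'   (strict: removal requires fraction > this).
#' @return The filtered counts tibble, gene order preserved. Warns (does not
#'   error) if every gene is removed.
#' @export
filter_low_expression <- function(counts, min_count = 10, max_fraction_below = 0.90) {
  m <- as_gene_matrix(counts)
  frac_below <- rowMeans(m < min_count)
  keep <- frac_below <= max_fraction_below
  if (!any(keep)) {
    warn("filter_low_expression removed every gene")
  }
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios library size factors
#'
#' For each sample j, `s_j` is the median over reference genes of
#' `count_gj / geomean_g(count)`, where reference genes are those with a
#' strictly positive geometric mean (all counts > 0). Factors are rescaled so
#' their geometric mean is 1. When no gene is expressed in every sample the
#' estimator falls back to total-count ratios with a warning.
#'
#' @param counts Wide counts tibble.
#' @return A named numeric vector of positive size factors (one per sample),
#'   geometric mean 1.
#' @export
size_factors <- function(counts) {
  m <- as_gene_matrix(counts)
  if (any(colSums(m) == 0)) abort("a sample has zero total counts")
  log_geo <- rowMeans(log(m))
  ref <- is.finite(log_geo)
  if (!any(ref)) {
    warn("no gene expressed in all samples; using total-count size factors")
    s <- colSums(m)
  } else {
    s <- apply(m[ref, , drop = FALSE], 2, function(col) {
      median(exp(log(col) - log_geo[ref]))
    })
  }
  s <- s / exp(mean(log(s)))
  setNames(s, colnames(m))
}

#' Shrunken log2 expression transform
#'
#' Computes a regularized log-scale expression matrix
#' `r0_gj = log2(count_gj / s_j + pseudocount)` followed by per-gene shrinkage
#' of the sample values toward the gene mean:
#' `r_gj = mean_g(r0) + (1 - lambda_g) * (r0_gj - mean_g(r0))` with
#' `lambda_g = (1 / m_g) / (1 / m_g + alpha_g)` bounded to `[0, max_shrink]`,
#' where `alpha_g` is the method-of-moments NB dispersion and `m_g` the mean
#' normalized count. `lambda_g` is the shot-noise (Poisson) share of the NB
#' variance at the gene's mean, so weakly expressed, shot-noise-dominated
#' genes are shrunk hardest while highly expressed genes keep their
#' between-sample differences; shrinkage never inflates the per-gene
#' variance. This is a simple documented variance-stabilizing transform;
#' downstream statistics only assume a monotone log-scale expression
#' measure.
#'
#' @param counts Wide counts tibble (typically after [filter_low_expression()]).
#' @param sf Size factors from [size_factors()]; computed if `NULL`.
#' @param pseudocount Added before the log (default 1).
#' @param max_shrink Upper bound on the shrinkage factor (default 0.95).
#' @return A wide tibble of transformed values with attributes
#'   `size_factors`, `pseudocount` and `max_shrink`.
#' @export
rlog_transform <- function(counts, sf = NULL, pseudocount = 1, max_shrink = 0.95) {
  m <- as_gene_matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  if (!setequal(names(sf), colnames(m))) {
    abort("size factor names do not match sample IDs")
  }
  sf <- sf[colnames(m)]
  if (any(sf <= 0)) abort("size factors must be strictly positive")
  q <- sweep(m, 2, sf, "/")
  r0 <- log2(q + pseudocount)
  alpha <- dispersion_mom(q)
  mg <- rowMeans(q)
  inv_m <- 1 / pmax(mg, .Machine$double.eps)
  lambda <- pmin(pmax(inv_m / (inv_m + alpha), 0), max_shrink)
  rbar <- rowMeans(r0)
  r <- rbar + (1 - lambda) * (r0 - rbar)
  out <- as_gene_tibble(r)
  attr(out, "size_factors") <- sf
  attr(out, "pseudocount") <- pseudocount
  attr(out, "max_shrink") <- max_shrink
  out
}

# Method-of-moments NB dispersion on normalized counts, by row or with a
# grouping of the columns; variance = mean + alpha * mean^2, floored.
dispersion_mom <- function(q, groups = NULL, floor = 1e-8) {
  if (is.null(groups)) groups <- rep("all", ncol(q))
  groups <- as.factor(groups)
  num <- matrix(0, nrow(q), 1)
  den <- matrix(0, nrow(q), 1)
  for (g in levels(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    mg <- rowMeans(q[, cols, drop = FALSE])
    vg <- apply(q[, cols, drop = FALSE], 1, var)
    w <- length(cols) - 1
    num <- num + w * (vg - mg)
    den <- den + w * mg^2
  }
  alpha <- as.numeric(num) / pmax(as.numeric(den), .Machine$double.eps)
  pmax(alpha, floor)
}
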