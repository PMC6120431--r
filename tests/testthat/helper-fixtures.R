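# Shared fixture builders. Everything is generated in code at test time.

# Minimal balanced design: one or two sites, 2 tides, times 0/6/24, n reps.
make_design <- function(sites = "BYQ", replicates = 3, times = c(0, 6, 24),
                        drop = character()) {
  grid <- expand.grid(replicate = seq_len(replicates), time_h = times,
                      tide = c("I", "S"), site = sites,
                      stringsAsFactors = FALSE)
  d <- tibble::tibble(
    sample_id = sprintf("%s_%s_%gh_r%d", grid$site, grid$tide, grid$time_h,
                        grid$replicate),
    site = grid$site, tide = grid$tide, time_h = grid$time_h,
    replicate = grid$replicate
  )
  d[!d$sample_id %in% drop, ]
}

# Wide expression tibble from a genes x samples matrix.
expr_tibble <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  tibble::as_tibble(cbind(data.frame(gene_id = rownames(m)), as.data.frame(m)))
}

# Gaussian expression data with a planted population offset and a planted
# stress displacement, both along a shared unit direction in gene space.
# Used for DAPC recovery checks.
make_axis_data <- function(n_genes = 500, replicates = 3, offset = 3,
                           delta = 2, noise = 0.05, seed = 1,
                           delta_S = delta, times = c(0, 6, 24)) {
  set.seed(seed)
  v <- rnorm(n_genes)
  v <- v / sqrt(sum(v^2))
  des <- make_design("X", replicates = replicates, times = times)
  m <- vapply(seq_len(nrow(des)), function(j) {
    dlt <- if (des$time_h[j] == 0) 0 else if (des$tide[j] == "I") delta else delta_S
    mu <- (des$tide[j] == "I") * offset * v + dlt * v
    mu + rnorm(n_genes, 0, noise)
  }, numeric(n_genes))
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- des$sample_id
  list(expr = expr_tibble(m), design = des, v = v)
}

# Per-sample axis scores with population separation, per-population shifts
# at the stressed times, a replicate batch effect and iid noise. Used for
# the mixed-model inference checks.
make_scores <- function(shift_I, shift_S, noise = 0.3, rep_sd = 0.3,
                        seed = 1) {
  set.seed(seed)
  grid <- expand.grid(replicate = 1:3, time_h = c(0, 6, 24),
                      group = c("I", "S"), stringsAsFactors = FALSE)
  u <- rnorm(3, 0, rep_sd)
  shift <- ifelse(grid$time_h == 0, 0,
                  ifelse(grid$group == "I", shift_I, shift_S))
  tibble::tibble(
    group = grid$group, time_h = grid$time_h, replicate = grid$replicate,
    score = ifelse(grid$group == "I", 1, -1) + shift + u[grid$replicate] +
      rnorm(nrow(grid), 0, noise)
  )
}

# Independent brute-force oracles -------------------------------------------

# BH step-up by direct enumeration of min over j >= i.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q
}

# Spearman via explicit mid-ranks and the Pearson sum formula.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Sign-concordance by explicit loop.
concordance_oracle <- function(E, D) {
  np <- 0L
  for (i in seq_along(E)) if (E[i] * D[i] > 0) np <- np + 1L
  c(np = np, nt = length(E))
}
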