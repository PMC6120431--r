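#' Run the full plasticity-versus-divergence pipeline
#'
#' Chains the whole analysis: low-expression filtering, median-of-ratios
#' normalization, the shrunken log transform, negative-binomial differential
#' expression for the divergence and plasticity contrasts of each site,
#' gene-set classification, the concordance table with its permutation null,
#' per-site DAPC with Bayesian shift inference, and the increased-plasticity
#' dynamics table.
#'
#' @param counts Wide counts tibble.
#' @param design Design tibble.
#' @param stress_times Stressed times (hours) to analyse.
#' @param alpha,use_adjusted Significance settings for [call_significant()].
#' @param within_site_rule Passed to [classify_genes()].
#' @param B Permutations for the concordance null.
#' @param n_mcmc Retained MCMC draws for shift inference.
#' @param seed Seed governing all randomness in the run.
#' @param out_dir If non-`NULL`, result tables are written there as TSV plus
#'   a `run_config.json` sidecar recording parameters and seed.
#' @return A list with elements `filtered_counts`, `size_factors`, `expr`,
#'   `de` (named list of DE tibbles), `gene_sets`, `concordance`,
#'   `dapc` (per site), `shift_inference` (per site), `dynamics`.
#' @export
run_plasticity_pipeline <- function(counts, design, stress_times = c(6, 24),
                                    alpha = 0.05, use_adjusted = TRUE,
                                    within_site_rule = "union",
                                    B = 1000, n_mcmc = 2800, seed = 1,
                                    out_dir = NULL) {
  design <- validate_design(design)
  sites <- unique(design$site)
  if (length(sites) != 2) abort("the pipeline expects exactly 2 sites")

  filtered <- filter_low_expression(counts)
  sf <- size_factors(filtered)
  expr <- rlog_transform(filtered, sf)

  contrasts <- c(
    lapply(sites, divergence_contrast),
    unlist(lapply(sites, function(s) {
      lapply(stress_times, function(t) plasticity_contrast(s, t))
    }), recursive = FALSE)
  )
  de <- lapply(contrasts, function(ct) {
    nb_wald_test(filtered, design, ct, sf = sf)
  })
  names(de) <- vapply(contrasts, function(ct) ct$name, character(1))
  names(de) <- sub("_0h$", "", names(de))  # divergence_<site>

  gene_sets <- classify_genes(de, sites = sites, stress_times = stress_times,
                              alpha = alpha, use_adjusted = use_adjusted,
                              within_site_rule = within_site_rule)

  concordance <- concordance_table(expr, design, gene_sets, sites = sites,
                                   times = stress_times, B = B, seed = seed)

  dapc <- lapply(sites, function(s) fit_dapc(expr, design, site = s))
  names(dapc) <- sites
  shift_inf <- lapply(seq_along(sites), function(i) {
    mcmc_shift_inference(dapc[[i]]$scores, n_retained = n_mcmc,
                         seed = seed + i)
  })
  names(shift_inf) <- sites

  dynamics <- increased_plasticity_counts(expr, design, gene_sets,
                                          sites = sites, times = stress_times)

  result <- list(
    filtered_counts = filtered, size_factors = sf, expr = expr, de = de,
    gene_sets = gene_sets, concordance = concordance, dapc = dapc,
    shift_inference = shift_inf, dynamics = dynamics
  )

  if (!is.null(out_dir)) {
    write_pipeline_results(result, out_dir, config = list(
      stress_times = stress_times, alpha = alpha, use_adjusted = use_adjusted,
      within_site_rule = within_site_rule, B = B, n_mcmc = n_mcmc, seed = seed
    ))
  }
  result
}

write_pipeline_results <- function(result, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tbl, name) {
    readr::write_tsv(tbl, file.path(out_dir, name), progress = FALSE)
  }
  for (nm in names(result$de)) {
    w(result$de[[nm]], sprintf("de_%s.tsv", nm))
  }
  w(tidy(result$gene_sets), "gene_sets.tsv")
  w(result$concordance, "concordance.tsv")
  for (site in names(result$dapc)) {
    w(result$dapc[[site]]$scores, sprintf("dapc_scores_%s.tsv", site))
    w(result$shift_inference[[site]]$contrasts,
      sprintf("shift_contrasts_%s.tsv", site))
  }
  w(result$dynamics$table, "dynamics.tsv")
  w(result$dynamics$comparisons, "dynamics_comparisons.tsv")
  w(tibble(sample_id = names(result$size_factors),
           size_factor = unname(result$size_factors)), "size_factors.tsv")
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
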