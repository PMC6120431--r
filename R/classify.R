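#' Gene-set classification from per-site significance calls
#'
#' The three gene sets of the analysis:
#' * **evolutionarily divergent (D)** — significantly different between tidal
#'   levels at baseline at *both* sites (intersection of the two per-site
#'   divergence calls);
#' * **concordantly plastic (P)** — significantly stress-responsive at *both*
#'   sites, where each site's two stressed-time call sets are first combined
#'   by `within_site_rule` (`"union"`: significant at either time, default;
#'   `"both"`: significant at both times);
#' * **adaptive plastic (A)** — genes in both D and P.
#'
#' @param div_site1,div_site2 Per-site divergence gene-ID sets.
#' @return Character vector of gene IDs.
#' @export
evolutionarily_divergent <- function(div_site1, div_site2) {
  intersect(div_site1, div_site2)
}

#' @rdname evolutionarily_divergent
#' @param plast_site1_t1,plast_site1_t2,plast_site2_t1,plast_site2_t2
#'   Per-site, per-stressed-time plasticity gene-ID sets.
#' @param within_site_rule `"union"` or `"both"` for combining a site's two
#'   stressed times.
#' @export
concordantly_plastic <- function(plast_site1_t1, plast_site1_t2,
                                 plast_site2_t1, plast_site2_t2,
                                 within_site_rule = c("union", "both")) {
  within_site_rule <- match.arg(within_site_rule)
  combine <- if (within_site_rule == "union") union else intersect
  intersect(combine(plast_site1_t1, plast_site1_t2),
            combine(plast_site2_t1, plast_site2_t2))
}

#' @rdname evolutionarily_divergent
#' @param D,P Divergent and concordantly plastic gene sets.
#' @export
adaptive_plastic <- function(D, P) {
  intersect(D, P)
}

#' Classify genes from a list of DE results
#'
#' Convenience wrapper: takes the six per-contrast DE tibbles of the standard
#' design (divergence at each site; plasticity at each site and stressed
#' time), applies [call_significant()] and assembles the three gene sets.
#'
#' @param de_list Named list of DE tibbles with names
#'   `divergence_<site1>`, `divergence_<site2>`,
#'   `plasticity_<site>_<t>h` for each site and stressed time.
#' @param sites Length-2 character vector of site labels.
#' @param stress_times Length-2 numeric vector of stressed times (hours).
#' @param alpha,use_adjusted Passed to [call_significant()].
#' @param within_site_rule Passed to [concordantly_plastic()].
#' @return An object of class `gene_sets`: list with character vectors `D`,
#'   `P`, `A` and a `provenance` list (thresholds and rule used).
#' @export
classify_genes <- function(de_list, sites, stress_times = c(6, 24),
                           alpha = 0.05, use_adjusted = TRUE,
                           within_site_rule = c("union", "both")) {
  within_site_rule <- match.arg(within_site_rule)
  need <- c(
    sprintf("divergence_%s", sites),
    sprintf("plasticity_%s_%gh", rep(sites, each = 2), rep(stress_times, 2))
  )
  missing <- setdiff(need, names(de_list))
  if (length(missing) > 0) {
    abort(sprintf("de_list is missing: %s", paste(missing, collapse = ", ")))
  }
  sig <- lapply(de_list[need], call_significant,
                alpha = alpha, use_adjusted = use_adjusted)
  D <- evolutionarily_divergent(sig[[sprintf("divergence_%s", sites[1])]],
                                sig[[sprintf("divergence_%s", sites[2])]])
  P <- concordantly_plastic(
    sig[[sprintf("plasticity_%s_%gh", sites[1], stress_times[1])]],
    sig[[sprintf("plasticity_%s_%gh", sites[1], stress_times[2])]],
    sig[[sprintf("plasticity_%s_%gh", sites[2], stress_times[1])]],
    sig[[sprintf("plasticity_%s_%gh", sites[2], stress_times[2])]],
    within_site_rule = within_site_rule
  )
  structure(
    list(
      D = D, P = P, A = adaptive_plastic(D, P),
      provenance = list(
        contrasts = need, alpha = alpha, use_adjusted = use_adjusted,
        within_site_rule = within_site_rule
      )
    ),
    class = "gene_sets"
  )
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("Gene sets:\n")
  cat(sprintf("  evolutionarily divergent (D): %d genes\n", length(x$D)))
  cat(sprintf("  concordantly plastic (P):     %d genes\n", length(x$P)))
  cat(sprintf("  adaptive plastic (A = D & P): %d genes\n", length(x$A)))
  invisible(x)
}

#' @export
tidy.gene_sets <- function(x, ...) {
  bind_rows(
    tibble(gene_id = x$D, gene_set = "evolutionarily_divergent"),
    tibble(gene_id = x$P, gene_set = "concordantly_plastic"),
    tibble(gene_id = x$A, gene_set = "adaptive_plastic")
  )
}
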