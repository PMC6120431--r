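#' Evolved change in plasticity per gene
#'
#' For each gene in a set, the difference between the intertidal and subtidal
#' plasticity magnitudes at stressed time t within one site:
#' `|D_g^I(t)| - |D_g^S(t)|`, where each `D` is the population's mean
#' expression change at t versus 0 h. Positive values mean the intertidal
#' population is the more plastic one for that gene.
#'
#' @inheritParams divergence_vector
#' @param time Stressed time (hours).
#' @return Named numeric vector indexed by the gene set.
#' @export
evolved_plasticity_change <- function(expr, design, gene_set, site, time,
                                      baseline_time = 0) {
  dI <- plasticity_vector(expr, design, gene_set, site, time, tide = "I",
                          baseline_time = baseline_time)
  dS <- plasticity_vector(expr, design, gene_set, site, time, tide = "S",
                          baseline_time = baseline_time)
  abs(dI) - abs(dS)
}

#' Increased-plasticity dynamics across gene sets
#'
#' Counts, per gene set, population and stressed time, the genes whose
#' plasticity is "increased", and compares the 6 h and 24 h proportions
#' within each population and set with a pooled two-proportion z-test.
#'
#' Two counting rules are available:
#' * `"vs_counterpart"` (default): a gene counts as increased for population
#'   P at time t when its plasticity magnitude in P strictly exceeds the
#'   magnitude in the other population at the same time.
#' * `"vs_zero"`: a gene counts as increased at time t when its plasticity
#'   magnitude at t strictly exceeds its magnitude at the other stressed
#'   time (within the same population).
#'
#' @inheritParams concordance_table
#' @param rule Counting rule, see Details.
#' @param sites Sites to evaluate (results are reported per site).
#' @return Object of class `plasticity_dynamics`: a `table` tibble
#'   (`gene_set`, `site`, `population`, `time_h`, `n_increased`, `n_total`,
#'   `percent`) and a `comparisons` tibble with the 6 h vs 24 h z-test
#'   p-value per (gene set, site, population).
#' @export
increased_plasticity_counts <- function(expr, design, gene_sets, sites,
                                        times = c(6, 24),
                                        rule = c("vs_counterpart", "vs_zero")) {
  rule <- match.arg(rule)
  design <- validate_design(design)
  sets <- if (inherits(gene_sets, "gene_sets")) {
    list(evolutionarily_divergent = gene_sets$D,
         concordantly_plastic = gene_sets$P,
         adaptive_plastic = gene_sets$A)
  } else {
    gene_sets
  }
  pops <- c("I", "S")
  rows <- list(); k <- 0
  for (set_name in names(sets)) {
    gs <- sets[[set_name]]
    for (site in sites) {
      if (length(gs) == 0) {
        for (pop in pops) {
          for (t in times) {
            k <- k + 1
            rows[[k]] <- tibble(
              gene_set = set_name, site = site, population = pop, time_h = t,
              n_increased = 0L, n_total = 0L, percent = NA_real_
            )
          }
        }
        next
      }
      mag <- list()
      for (pop in pops) {
        for (t in times) {
          mag[[paste(pop, t)]] <-
            abs(plasticity_vector(expr, design, gs, site, t, tide = pop))
        }
      }
      for (pop in pops) {
        other <- setdiff(pops, pop)
        for (t in times) {
          inc <- if (rule == "vs_counterpart") {
            mag[[paste(pop, t)]] > mag[[paste(other, t)]]
          } else {
            t_other <- setdiff(times, t)[1]
            mag[[paste(pop, t)]] > mag[[paste(pop, t_other)]]
          }
          k <- k + 1
          rows[[k]] <- tibble(
            gene_set = set_name, site = site, population = pop, time_h = t,
            n_increased = sum(inc), n_total = length(inc),
            percent = round_half_up(100 * mean(inc), 2)
          )
        }
      }
    }
  }
  tab <- bind_rows(rows)

  comparisons <- tab %>%
    group_by(.data$gene_set, .data$site, .data$population) %>%
    summarise(
      p_value = two_prop_z(
        .data$n_increased[.data$time_h == times[1]],
        .data$n_total[.data$time_h == times[1]],
        .data$n_increased[.data$time_h == times[2]],
        .data$n_total[.data$time_h == times[2]]
      ),
      .groups = "drop"
    ) %>%
    mutate(significant = !is.na(.data$p_value) & .data$p_value < 0.05)

  structure(list(table = tab, comparisons = comparisons, rule = rule),
            class = "plasticity_dynamics")
}

# Pooled two-proportion z-test, two-sided, no continuity correction.
two_prop_z <- function(x1, n1, x2, n2) {
  if (length(x1) != 1 || length(x2) != 1 || n1 == 0 || n2 == 0) return(NA_real_)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) return(if (p1 == p2) 1 else 0)
  2 * pnorm(-abs((p1 - p2) / se))
}

#' @export
print.plasticity_dynamics <- function(x, ...) {
  cat(sprintf("Increased-plasticity dynamics (rule: %s)\n", x$rule))
  print(x$table)
  cat("6 h vs 24 h comparisons:\n")
  print(x$comparisons)
  invisible(x)
}

#' @export
tidy.plasticity_dynamics <- function(x, ...) {
  x$table
}

#' @export
glance.plasticity_dynamics <- function(x, ...) {
  tibble(
    rule = x$rule,
    n_significant = sum(x$comparisons$significant, na.rm = TRUE),
    n_comparisons = nrow(x$comparisons)
  )
}
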