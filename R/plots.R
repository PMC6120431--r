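#' Plot a divergence-plasticity concordance test
#'
#' Scatter of per-gene plastic change against evolved divergence; the
#' quadrants through the origin separate concordant (same-sign) from
#' discordant genes.
#'
#' @param object A `concordance_test` from [permutation_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concordance_test <- function(object, ...) {
  d <- tidy(object)
  s <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$divergence, y = .data$plasticity,
                                  colour = .data$concordant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      title = sprintf("%s, %s", s$gene_set, s$group),
      subtitle = sprintf("Np/Nt = %d/%d (%.2f%%), rho = %.2f, perm p = %.3g",
                         s$np, s$nt, s$percent, s$rho, s$p_perm),
      x = "evolved divergence (I - S at 0 h, rlog)",
      y = "plastic change (stressed - 0 h, rlog)",
      colour = "concordant"
    ) +
    ggplot2::theme_minimal()
}

#' Plot DAPC axis scores by population and time
#'
#' @param object A `tidal_dapc` from [fit_dapc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tidal_dapc <- function(object, ...) {
  d <- object$scores
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$time_h), y = .data$score,
                                  colour = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3),
                        size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "line",
                          ggplot2::aes(group = .data$group)) +
    ggplot2::labs(x = "time under heat stress (h)",
                  y = "score on unstressed discriminant axis",
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' Plot increased-plasticity dynamics
#'
#' Bar chart of the percent of genes with increased plasticity per gene set,
#' population and time.
#'
#' @param object A `plasticity_dynamics` from [increased_plasticity_counts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plasticity_dynamics <- function(object, ...) {
  d <- object$table
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$time_h), y = .data$percent,
                                  fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(.data$site ~ .data$gene_set) +
    ggplot2::labs(x = "time under heat stress (h)",
                  y = "% genes with increased plasticity",
                  fill = "population") +
    ggplot2::theme_minimal()
}
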