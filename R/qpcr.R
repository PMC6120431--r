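#' Read a qPCR Ct table
#'
#' Expects CSV columns `gene`, `sample_id`, `ct` (PCR cycles, finite and
#' positive); technical duplicates (repeated `gene`/`sample_id` rows) are
#' averaged on the Ct scale.
#'
#' @param path CSV path.
#' @return Tibble with one row per (gene, sample_id) and the mean `ct`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Ct file not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_ct_table(tbl)
}

#' @rdname read_ct_table
#' @param tbl Raw Ct tibble.
#' @export
validate_ct_table <- function(tbl) {
  need <- c("gene", "sample_id", "ct")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("Ct table is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(tbl$ct)) || any(tbl$ct <= 0)) {
    abort("Ct values must be finite and positive")
  }
  tbl %>%
    group_by(.data$gene, .data$sample_id) %>%
    summarise(ct = mean(.data$ct), .groups = "drop")
}

ct_lookup <- function(tbl, gene, sample) {
  v <- tbl$ct[tbl$gene == gene & tbl$sample_id == sample]
  if (length(v) != 1) {
    abort(sprintf("missing Ct for gene %s, sample %s", gene, sample))
  }
  v
}

#' Livak relative expression (2^-ddCt)
#'
#' Relative expression of `gene` in `sample` against the calibrator
#' condition: `dCt = Ct_gene - Ct_reference` within each sample,
#' `ddCt = dCt_sample - dCt_calibrator`, fold change `2^-ddCt`. The result is
#' strictly positive, equals 1 when `sample` is the calibrator, and is
#' invariant to any Ct offset applied to both the target and reference gene
#' of a sample.
#'
#' @param table Ct tibble (see [read_ct_table()]); technical duplicates are
#'   averaged on the Ct scale first.
#' @param gene Target gene.
#' @param sample Sample of interest.
#' @param calibrator_sample Calibrator sample (e.g. the 0 h condition).
#' @param reference Reference (housekeeping) gene.
#' @return Positive fold change (numeric scalar).
#' @examples
#' ct <- tibble::tibble(
#'   gene = c("hsp70", "ef1a", "hsp70", "ef1a"),
#'   sample_id = c("t6", "t6", "t0", "t0"),
#'   ct = c(18, 15, 20, 15)
#' )
#' livak_fold_change(ct, "hsp70", "t6", "t0", reference = "ef1a") # 4
#' @export
livak_fold_change <- function(table, gene, sample, calibrator_sample,
                              reference) {
  tbl <- validate_ct_table(table)
  dct_sample <- ct_lookup(tbl, gene, sample) - ct_lookup(tbl, reference, sample)
  dct_cal <- ct_lookup(tbl, gene, calibrator_sample) -
    ct_lookup(tbl, reference, calibrator_sample)
  2^(-(dct_sample - dct_cal))
}

#' Relative expression for every gene and sample
#'
#' Vectorized [livak_fold_change()] over all non-reference genes and all
#' samples, with a shared calibrator sample.
#'
#' @inheritParams livak_fold_change
#' @return Tibble with `gene`, `sample_id`, `fold_change`.
#' @export
relative_expression <- function(table, reference, calibrator_sample) {
  tbl <- validate_ct_table(table)
  genes <- setdiff(unique(tbl$gene), reference)
  samples <- unique(tbl$sample_id)
  purrr::map_dfr(genes, function(g) {
    purrr::map_dfr(samples, function(s) {
      tibble(gene = g, sample_id = s,
             fold_change = livak_fold_change(tbl, g, s, calibrator_sample,
                                             reference))
    })
  })
}

#' Average-linkage clustering of relative-expression profiles
#'
#' Convenience: hierarchical clustering (Euclidean distance, average linkage)
#' of genes by their fold-change profiles across samples.
#'
#' @param rel Tibble from [relative_expression()].
#' @return An [stats::hclust] object.
#' @export
cluster_expression_profiles <- function(rel) {
  wide <- tidyr::pivot_wider(rel, names_from = "sample_id",
                             values_from = "fold_change")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene
  stats::hclust(stats::dist(m), method = "average")
}
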