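# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals. base::round() rounds half to
# even, which disagrees with the reporting convention used for concordance
# percentages (e.g. 90.625 -> 90.63).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Convert a wide counts/expression tibble (gene_id + one column per sample)
# to a numeric matrix with gene rownames.
as_gene_matrix <- function(tbl, value_name = "counts") {
  stopifnot(is.data.frame(tbl))
  if (!"gene_id" %in% names(tbl)) {
    abort(sprintf("%s table must have a 'gene_id' column", value_name))
  }
  m <- as.matrix(tbl[setdiff(names(tbl), "gene_id")])
  if (!is.numeric(m)) {
    abort(sprintf("%s table has non-numeric sample columns", value_name))
  }
  rownames(m) <- tbl$gene_id
  m
}

# Inverse of as_gene_matrix().
as_gene_tibble <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- tibble(gene_id = rownames(m)) %>% dplyr::bind_cols(out)
  out
}

# Sample IDs of a design subset. Predicates are evaluated with dplyr::filter.
design_samples <- function(design, ...) {
  dplyr::filter(design, ...)$sample_id
}

# Check that the sample columns of a counts/expr table exactly match the
# design's sample_id set (order-insensitive), then return the matrix with
# columns reordered to design order.
align_to_design <- function(tbl, design, value_name = "counts") {
  m <- as_gene_matrix(tbl, value_name)
  ids <- design$sample_id
  if (!setequal(colnames(m), ids)) {
    missing_in_tbl <- setdiff(ids, colnames(m))
    extra_in_tbl <- setdiff(colnames(m), ids)
    abort(sprintf(
      "sample IDs of %s and design do not match (missing: %s; extra: %s)",
      value_name,
      paste(missing_in_tbl, collapse = ","),
      paste(extra_in_tbl, collapse = ",")
    ))
  }
  m[, ids, drop = FALSE]
}

# Row means over a set of sample columns; errors if the group is empty.
group_row_means <- function(m, samples, what = "group") {
  if (length(samples) == 0) {
    abort(sprintf("no samples in %s", what))
  }
  rowMeans(m[, samples, drop = FALSE])
}
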