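#' Read a gene-by-sample count table
#'
#' Reads raw integer counts either from a TSV file (header row of sample IDs,
#' first column of gene IDs) or from a MatrixMarket `.mtx` file accompanied by
#' `<stem>.genes.txt` and `<stem>.samples.txt` sidecar files (one ID per line).
#' Row and column order are preserved from the file.
#'
#' @param path Path to the counts file.
#' @param format `"tsv"` (default) or `"mtx"`.
#' @return A wide tibble with a `gene_id` column followed by one integer
#'   column per sample, validated by [validate_counts()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_counts(example_counts(), tf)
#' counts <- read_counts(tf)
#' @seealso [write_counts()], [read_design()]
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("counts file not found: %s", path))
  if (format == "tsv") {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    names(tbl)[1] <- "gene_id"
    tbl$gene_id <- as.character(tbl$gene_id)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    genes_file <- paste0(stem, ".genes.txt")
    samples_file <- paste0(stem, ".samples.txt")
    if (!file.exists(genes_file) || !file.exists(samples_file)) {
      abort(sprintf("mtx sidecar files missing: %s / %s", genes_file, samples_file))
    }
    rownames(m) <- readr::read_lines(genes_file, progress = FALSE)
    colnames(m) <- readr::read_lines(samples_file, progress = FALSE)
    tbl <- as_gene_tibble(m)
  }
  tbl <- validate_counts(tbl)
  # store counts as integers (validated integral above)
  tbl[-1] <- lapply(tbl[-1], as.integer)
  tbl
}

#' Write a count table to TSV
#'
#' @param counts Wide counts tibble (`gene_id` + sample columns).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Validate a count table
#'
#' Checks the count-table contract: a `gene_id` column with unique IDs, unique
#' sample column names, and non-negative integral entries. Violations raise an
#' error naming the offending gene/sample.
#'
#' @param counts Wide counts tibble.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_counts <- function(counts) {
  m <- as_gene_matrix(counts)
  if (anyDuplicated(rownames(m))) {
    dup <- rownames(m)[duplicated(rownames(m))][1]
    abort(sprintf("duplicate gene ID: %s", dup))
  }
  if (anyDuplicated(colnames(m))) {
    dup <- colnames(m)[duplicated(colnames(m))][1]
    abort(sprintf("duplicate sample ID: %s", dup))
  }
  if (anyNA(m)) abort("counts contain missing values")
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "invalid count %s at gene %s, sample %s (must be a non-negative integer)",
      format(m[bad[1, 1], bad[1, 2]]), rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    ))
  }
  counts
}

#' Read a sample design table
#'
#' Reads per-sample metadata from CSV with required columns `sample_id`,
#' `site`, `tide`, `time_h`, `replicate`. Factor levels are recorded in file
#' order; the baseline time is the smallest `time_h`. Every
#' `(site, tide, time_h)` cell must contain at least two replicates (needed
#' for dispersion estimation downstream).
#'
#' @param path Path to the design CSV.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(sprintf("design file not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_design(tbl)
}

#' Validate a sample design table
#'
#' @param design Design tibble with columns `sample_id`, `site`, `tide`,
#'   `time_h`, `replicate`.
#' @param tide_levels Allowed tidal levels; default intertidal `"I"` and
#'   subtidal `"S"`.
#' @return The design as a tibble with `site`/`tide` as character, `time_h`
#'   numeric, and attribute `baseline_time` set to the smallest time.
#' @export
validate_design <- function(design, tide_levels = c("I", "S")) {
  required <- c("sample_id", "site", "tide", "time_h", "replicate")
  missing <- setdiff(required, names(design))
  if (length(missing) > 0) {
    abort(sprintf("design is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  design <- as_tibble(design)
  design$sample_id <- as.character(design$sample_id)
  design$site <- as.character(design$site)
  design$tide <- as.character(design$tide)
  design$time_h <- as.numeric(design$time_h)
  design$replicate <- as.integer(design$replicate)
  if (anyDuplicated(design$sample_id)) {
    abort(sprintf(
      "duplicate sample ID in design: %s",
      design$sample_id[duplicated(design$sample_id)][1]
    ))
  }
  bad_tide <- setdiff(unique(design$tide), tide_levels)
  if (length(bad_tide) > 0) {
    abort(sprintf("unknown tide level(s): %s", paste(bad_tide, collapse = ", ")))
  }
  if (any(design$replicate < 1)) abort("replicate must be a positive integer")
  cells <- design %>%
    dplyr::count(.data$site, .data$tide, .data$time_h)
  small <- dplyr::filter(cells, .data$n < 2)
  if (nrow(small) > 0) {
    abort(sprintf(
      "design cell(s) with fewer than 2 replicates: %s",
      paste(sprintf("%s/%s/%gh (n=%d)", small$site, small$tide, small$time_h, small$n),
            collapse = "; ")
    ))
  }
  attr(design, "baseline_time") <- min(design$time_h)
  design
}

#' A tiny example count table
#'
#' Three genes by two samples; used in documentation examples.
#' @return A wide counts tibble.
#' @export
example_counts <- function() {
  tibble(
    gene_id = c("g1", "g2", "g3"),
    s1 = c(5L, 10L, 0L),
    s2 = c(0L, 2L, 7L)
  )
}
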