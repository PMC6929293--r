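# Plain-text IO: bin-count matrices, FISH count tables, bundled observed
# tables.

#' Write / read a bin-count matrix
#'
#' The on-disk format is a TSV whose first three columns are `chrom`,
#' `start`, `end` (one row per bin, grid order) and whose remaining columns
#' are cells.
#'
#' @param counts Numeric matrix (bins x cells) or data frame of per-cell
#'   count columns.
#' @param grid A [bin_grid()].
#' @param path Output path.
#' @return `path` invisibly (writer); a list `grid`/`counts` (reader).
#' @export
write_bin_matrix <- function(counts, grid, path) {
  counts <- as.data.frame(counts)
  if (nrow(counts) != nrow(grid)) {
    abort("`counts` must have one row per grid bin")
  }
  out <- dplyr::bind_cols(grid[, c("chrom", "start", "end")], counts)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_bin_matrix
#' @export
read_bin_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("chrom", "start", "end"), "bin matrix")
  grid <- df[, c("chrom", "start", "end")]
  grid$bin <- seq_len(nrow(grid))
  list(
    grid = grid[, c("bin", "chrom", "start", "end")],
    counts = as.matrix(df[, setdiff(names(df), c("chrom", "start", "end")),
                          drop = FALSE])
  )
}

#' Bundled FISH count table for SNCA mosaicism
#'
#' Observed counts of cells analysed and cells with unique SNCA gains, per
#' disease group (MSA, PD, other Lewy-body disease, control), brain region
#' (cingulate cortex, substantia nigra) and cell type (neuron / non-neuron,
#' or neuromelanin-positive / -negative in the nigra). Rows tagged
#' `prior_control` are the substantia nigra control counts from an earlier
#' survey of the same assay, used for the large-sample comparisons.
#'
#' @return Tibble with columns `disease`, `region`, `cell_type`,
#'   `n_analysed`, `n_gain`, `cohort`.
#' @export
snca_fish_counts <- function() {
  path <- system.file("extdata", "snca_fish_counts.tsv",
                      package = "mosaicnv", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Bundled 2x2 tables relating SNCA gains to inclusions
#'
#' Observed cell tallies cross-classifying CNV (SNCA gain) status against
#' alpha-synuclein inclusion status, stratified by disease group and cell
#' type, plus the oligodendrocyte-marker (olig2) and pons strata. Layout:
#' `a` = CNV+ with inclusion, `b` = CNV+ without, `c` = CNV- with, `d` =
#' CNV- without (for the olig2 stratum the "exposure" is olig2 positivity
#' and the outcome an SNCA gain).
#'
#' @return Tibble with columns `stratum`, `disease`, `cell_type`, `a`, `b`,
#'   `c`, `d`.
#' @export
snca_inclusion_tables <- function() {
  path <- system.file("extdata", "snca_inclusion_tables.tsv",
                      package = "mosaicnv", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write calls to a BED-flavoured TSV
#'
#' Columns: chrom, start, end, then call annotations (cell, copy number,
#' kind, filter status).
#'
#' @param calls Call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  cols <- intersect(
    c("chrom", "start", "end", "cell_id", "n_bins", "cn_real", "cn_int",
      "kind", "event_class", "kept", "reason"),
    names(calls)
  )
  readr::write_tsv(calls[, cols], path, progress = FALSE)
  invisible(path)
}
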