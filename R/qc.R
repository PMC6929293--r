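#' Quality-control thresholds for single-cell profiles
#'
#' Defaults follow the gates used for amplified single-nucleus sequencing:
#' more than 800,000 reads, confidence score at least 0.8, and MAPD below
#' 0.3.
#'
#' @param min_reads Minimum total reads (exclusive bound).
#' @param min_confidence Minimum confidence score (inclusive bound).
#' @param max_mapd Maximum MAPD (exclusive bound).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(min_reads = 800000, min_confidence = 0.8,
                          max_mapd = 0.3) {
  if (min_reads <= 0 || min_confidence <= 0 || max_mapd <= 0) {
    abort("QC thresholds must be positive")
  }
  list(min_reads = min_reads, min_confidence = min_confidence,
       max_mapd = max_mapd)
}

#' Compute per-cell quality metrics
#'
#' Three gates decide whether a cell's profile is analysed:
#' * **reads** — total read count must exceed `min_reads`;
#' * **MAPD** — the median absolute deviation between consecutive bins
#'   (computed on ploidy-scaled linear copy-number values, within
#'   chromosomes, autosomes only), a measure of local amplification noise;
#' * **confidence** — the fraction of autosomal bins whose segment mean copy
#'   number lies within 0.25 of its nearest integer, measuring how well the
#'   profile conforms to integer copy-number states.
#'
#' @param total_reads Total reads of the cell.
#' @param values Normalised per-bin values (see [normalize_counts()]).
#' @param segments Segment tibble from [segment_profile()].
#' @param ploidy Fitted ploidy scale from [fit_ploidy()].
#' @param grid,genome Bin grid and genome model.
#' @param thresholds A [qc_thresholds()] list.
#' @return One-row tibble: `total_reads`, `mapd`, `confidence`, `pass`,
#'   `fail_reasons` (comma-separated, empty when passing).
#' @export
compute_qc <- function(total_reads, values, segments, ploidy, grid, genome,
                       thresholds = qc_thresholds()) {
  auto <- grid$chrom %in% autosomes(genome)
  cn <- ploidy * values
  same_chrom <- grid$chrom[-1] == grid$chrom[-nrow(grid)]
  pair_auto <- auto[-1] & auto[-length(auto)] & same_chrom
  if (!any(pair_auto)) abort("need at least 2 bins per chromosome")
  mapd <- median(abs(diff(cn))[pair_auto])

  seg_cn <- ploidy * per_bin_segment_means(segments, nrow(grid))
  seg_cn <- seg_cn[auto & !is.na(seg_cn)]
  confidence <- mean(abs(seg_cn - round(seg_cn)) <= 0.25)

  reasons <- c(
    if (total_reads <= thresholds$min_reads) "reads",
    if (confidence < thresholds$min_confidence) "confidence",
    if (mapd >= thresholds$max_mapd) "mapd"
  )
  tibble(
    total_reads = total_reads,
    mapd = mapd,
    confidence = confidence,
    pass = length(reasons) == 0L,
    fail_reasons = paste(reasons, collapse = ",")
  )
}
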