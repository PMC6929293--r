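#' Read a BED file into a tibble of intervals
#'
#' Parses BED3+ (tab-separated, 0-based half-open). `track`/`browser` header
#' lines and `#` comments are skipped. Malformed lines (fewer than three
#' fields, non-numeric or inverted coordinates) are reported with their line
#' numbers; intervals on chromosomes absent from `genome` either warn and are
#' dropped, or fail, per `on_unknown_chrom`.
#'
#' @param path Path to a BED file.
#' @param genome Optional [genome_model()] used to check chromosome names.
#' @param on_unknown_chrom `"warn"` (drop with a warning) or `"error"`.
#'
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name` and `score`.
#' @export
read_bed <- function(path, genome = NULL,
                     on_unknown_chrom = c("warn", "error")) {
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  if (!file.exists(path)) {
    abort(sprintf("BED file not found: %s", path))
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track|browser)\\b", lines) & !startsWith(lines, "#") &
    nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 3L
  starts <- suppressWarnings(as.numeric(vapply(fields, function(f) f[2], "")))
  ends <- suppressWarnings(as.numeric(vapply(fields, function(f) f[3], "")))
  bad <- bad | is.na(starts) | is.na(ends) | starts < 0 | starts >= ends
  if (any(bad)) {
    abort(sprintf(
      "malformed BED line(s) at: %s",
      paste(idx[bad], collapse = ", ")
    ))
  }
  out <- tibble(
    chrom = vapply(fields, function(f) f[1], ""),
    start = starts,
    end = ends
  )
  if (all(nf >= 4L)) out$name <- vapply(fields, function(f) f[4], "")
  if (all(nf >= 5L)) {
    out$score <- suppressWarnings(
      as.numeric(vapply(fields, function(f) f[5], ""))
    )
  }
  if (!is.null(genome)) {
    unknown <- !(out$chrom %in% names(genome$chrom_lengths))
    if (any(unknown)) {
      msg <- sprintf("%d interval(s) on chromosome(s) not in the genome model",
                     sum(unknown))
      if (on_unknown_chrom == "error") abort(msg)
      warn(paste0(msg, "; dropped"))
      out <- out[!unknown, ]
    }
  }
  out
}

#' Write intervals to a BED file
#'
#' Writes BED3 (plus `name` and `score` columns when present) with intervals
#' sorted by chromosome then start, so output ordering is stable regardless of
#' input order.
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end` and optional
#'   `name`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals, name = "intervals")
  cols <- intersect(c("chrom", "start", "end", "name", "score"),
                    names(intervals))
  out <- intervals[order(intervals$chrom, intervals$start, intervals$end),
                   cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
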