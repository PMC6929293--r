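#' Define a genome model
#'
#' A genome model is the coordinate system everything else lives on: a set of
#' named chromosomes with lengths, optional centromere intervals, and the set
#' of chromosomes treated as non-autosomal. All coordinates in the package are
#' 0-based half-open (BED convention).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#'   Names are normalised to the `"chr"`-prefixed dialect; unprefixed names
#'   are mapped with a warning.
#' @param centromeres Optional tibble with columns `chrom`, `start`, `end`
#'   giving one centromere interval per chromosome. Must lie within the
#'   chromosome.
#' @param sex_chroms Character vector of chromosome names treated as
#'   non-autosomal (default `c("chrX", "chrY")`).
#'
#' @return An object of class `genome_model`: a list with elements
#'   `chrom_lengths` (named numeric), `centromeres` (tibble or `NULL`) and
#'   `sex_chroms` (character).
#' @export
#' @examples
#' genome_model(c(chr1 = 1e6, chr2 = 5e5))
genome_model <- function(chrom_lengths, centromeres = NULL,
                         sex_chroms = c("chrX", "chrY")) {
  if (length(chrom_lengths) == 0L || is.null(names(chrom_lengths)) ||
      any(!nzchar(names(chrom_lengths)))) {
    abort("`chrom_lengths` must be a non-empty named vector")
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    abort("all chromosome lengths must be positive")
  }
  names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
  sex_chroms <- normalize_chrom(sex_chroms, quiet = TRUE)
  if (anyDuplicated(names(chrom_lengths))) {
    abort("duplicated chromosome names after normalisation")
  }
  if (!is.null(centromeres)) {
    centromeres <- as_tibble(centromeres)
    assert_columns(centromeres, c("chrom", "start", "end"), "centromeres")
    centromeres$chrom <- normalize_chrom(centromeres$chrom, quiet = TRUE)
    bad <- !(centromeres$chrom %in% names(chrom_lengths))
    if (any(bad)) {
      abort(sprintf("centromere chromosome(s) not in genome: %s",
                    paste(unique(centromeres$chrom[bad]), collapse = ", ")))
    }
    within <- centromeres$start >= 0 &
      centromeres$start < centromeres$end &
      centromeres$end <= chrom_lengths[centromeres$chrom]
    if (!all(within)) {
      abort("centromere intervals must lie within their chromosome")
    }
  }
  structure(
    list(
      chrom_lengths = chrom_lengths,
      centromeres = centromeres,
      sex_chroms = intersect(sex_chroms, names(chrom_lengths))
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %d chromosomes, %.1f Mb total (%d non-autosomal)\n",
    length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6, length(x$sex_chroms)
  ))
  invisible(x)
}

# chromosomes counted as autosomes for normalisation / QC
autosomes <- function(genome) {
  setdiff(names(genome$chrom_lengths), genome$sex_chroms)
}

# Map chromosome names into the "chr"-prefixed dialect.
normalize_chrom <- function(chrom, quiet = FALSE) {
  chrom <- as.character(chrom)
  bare <- !startsWith(chrom, "chr")
  if (any(bare)) {
    if (!quiet) {
      warn(sprintf("mapping %d chromosome name(s) to the 'chr' dialect",
                   sum(bare)))
    }
    chrom[bare] <- paste0("chr", chrom[bare])
  }
  chrom
}

#' Tile a genome into fixed-width bins
#'
#' Partitions every chromosome into consecutive, non-overlapping bins of
#' uniform width; the last bin of a chromosome is shortened to the chromosome
#' end when the length is not a multiple of the width. Bins are ordered by
#' chromosome (genome order) then coordinate.
#'
#' @param genome A [genome_model()].
#' @param width Bin width in bp (e.g. `250000`).
#'
#' @return A tibble with columns `bin` (1-based index), `chrom`, `start`,
#'   `end` (0-based half-open).
#' @export
#' @examples
#' g <- genome_model(c(chr1 = 1.1e6))
#' bin_grid(g, 5e5)
bin_grid <- function(genome, width) {
  stopifnot(inherits(genome, "genome_model"))
  assert_number(width, "width", positive = TRUE)
  grid <- purrr::map2_dfr(
    names(genome$chrom_lengths), unname(genome$chrom_lengths),
    function(chrom, len) {
      starts <- seq(0, len - 1, by = width)
      tibble(chrom = chrom, start = starts, end = pmin(starts + width, len))
    }
  )
  grid$bin <- seq_len(nrow(grid))
  grid[, c("bin", "chrom", "start", "end")]
}

# Validate a tibble of genomic intervals against a genome model.
validate_intervals <- function(df, genome = NULL, name = "intervals") {
  assert_columns(df, c("chrom", "start", "end"), name)
  if (any(df$start < 0) || any(df$start >= df$end)) {
    abort(sprintf("`%s` contains intervals with start < 0 or start >= end",
                  name))
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(df$chrom), names(genome$chrom_lengths))
    if (length(unknown) > 0L) {
      abort(sprintf("`%s` refers to unknown chromosome(s): %s",
                    name, paste(unknown, collapse = ", ")))
    }
    over <- df$end > genome$chrom_lengths[df$chrom]
    if (any(over)) {
      abort(sprintf("`%s` contains intervals past the chromosome end", name))
    }
  }
  invisible(df)
}
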