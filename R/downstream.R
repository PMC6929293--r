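# Post-calling analytics: clonality, composition, sizes, inclusion
# association, gene annotation.

#' Detect possibly clonal CNVs across cells
#'
#' Single-linkage grouping of same-kind calls whose left boundaries AND
#' right boundaries each differ by at most `tolerance` (default 1 Mb).
#' Groups spanning at least two distinct cells are reported; copy number may
#' differ within a group (a clone can be called at copy number 3 in one cell
#' and 4 in another). Grouping is symmetric and order-independent.
#'
#' @param calls Call tibble with `cell_id`, `chrom`, `start`, `end`, `kind`.
#' @param tolerance Maximum per-boundary distance in bp (default 1e6).
#' @return Tibble with one row per clone group: `clone_id`, `n_members`,
#'   `n_cells`, `chrom`, `consensus_start`, `consensus_end`,
#'   `max_boundary_spread` (bp), `members` (list of call row indices into
#'   `calls`), `cell_ids` (list).
#' @export
detect_clones <- function(calls, tolerance = 1e6) {
  empty <- tibble(
    clone_id = integer(), n_members = integer(), n_cells = integer(),
    chrom = character(), consensus_start = double(),
    consensus_end = double(), max_boundary_spread = double(),
    members = list(), cell_ids = list()
  )
  if (nrow(calls) < 2L) {
    return(empty)
  }
  n <- nrow(calls)
  # single linkage via union-find over matching pairs
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(calls$chrom, calls$start)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (calls$chrom[j] != calls$chrom[i] ||
          calls$start[j] - calls$start[i] > tolerance) {
        break
      }
      if (calls$kind[i] == calls$kind[j] &&
          abs(calls$end[i] - calls$end[j]) <= tolerance) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  groups <- purrr::keep(groups, function(g) {
    length(g) >= 2L && length(unique(calls$cell_id[g])) >= 2L
  })
  if (length(groups) == 0L) {
    return(empty)
  }
  purrr::imap_dfr(unname(groups), function(g, gi) {
    spread <- max(max(calls$start[g]) - min(calls$start[g]),
                  max(calls$end[g]) - min(calls$end[g]))
    tibble(
      clone_id = gi,
      n_members = length(g),
      n_cells = length(unique(calls$cell_id[g])),
      chrom = calls$chrom[g[1]],
      consensus_start = median(calls$start[g]),
      consensus_end = median(calls$end[g]),
      max_boundary_spread = spread,
      members = list(g),
      cell_ids = list(unique(calls$cell_id[g]))
    )
  })
}

#' Summarise gain/loss composition per cell type
#'
#' Tallies kept sub-chromosomal calls (pure aneusomies and polyploid cells
#' are excluded) per cell type: numbers of gains and losses, gain fraction
#' (percent, 1 decimal), per-cell CNV counts and the fraction of cells with
#' at least one CNV. A Fisher exact comparison of the gain:loss split
#' between the first two cell types is attached as an attribute
#' `"fisher_p"` when both are present.
#'
#' @param calls Filtered call tibble (with `kept` and `event_class`).
#' @param cell_meta Tibble with `cell_id` and `cell_type` for every analysed
#'   cell (including cells without calls, so per-cell fractions are correct).
#' @return Tibble with one row per cell type: `cell_type`, `n_gain`,
#'   `n_loss`, `n_cnv`, `gain_pct`, `n_cells`, `n_cells_with_cnv`,
#'   `pct_cells_with_cnv`.
#' @export
summarize_composition <- function(calls, cell_meta) {
  assert_columns(cell_meta, c("cell_id", "cell_type"), "cell_meta")
  unknown <- setdiff(calls$cell_id, cell_meta$cell_id)
  if (length(unknown) > 0L) {
    abort(sprintf("calls from cell(s) missing in `cell_meta`: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  cnvs <- calls |>
    filter(.data$kept, .data$event_class == "sub_chromosomal") |>
    left_join(cell_meta, by = "cell_id")
  out <- cell_meta |>
    group_by(.data$cell_type) |>
    summarise(n_cells = dplyr::n_distinct(.data$cell_id), .groups = "drop")
  tallies <- cnvs |>
    group_by(.data$cell_type) |>
    summarise(
      n_gain = sum(.data$kind == "gain"),
      n_loss = sum(.data$kind == "loss"),
      n_cnv = n(),
      n_cells_with_cnv = dplyr::n_distinct(.data$cell_id),
      .groups = "drop"
    )
  out <- out |>
    left_join(tallies, by = "cell_type") |>
    mutate(
      across(c("n_gain", "n_loss", "n_cnv", "n_cells_with_cnv"),
             ~ tidyr::replace_na(.x, 0L)),
      gain_pct = round(100 * .data$n_gain / pmax(.data$n_cnv, 1), 1),
      pct_cells_with_cnv = round(100 * .data$n_cells_with_cnv /
                                   .data$n_cells, 1)
    ) |>
    select("cell_type", "n_gain", "n_loss", "n_cnv", "gain_pct", "n_cells",
           "n_cells_with_cnv", "pct_cells_with_cnv")
  if (nrow(out) >= 2L && all(out$n_cnv[1:2] > 0)) {
    attr(out, "fisher_p") <- fisher_exact(out$n_gain[1], out$n_loss[1],
                                          out$n_gain[2], out$n_loss[2])
  }
  out
}

#' Compare CNV sizes between two groups
#'
#' Two-sided Mann-Whitney U test with midranks on sizes (reported in Mb,
#' medians to 2 decimals).
#'
#' @param sizes_a,sizes_b Numeric vectors of CNV sizes in Mb.
#' @return Tibble with `median_a`, `median_b`, `u`, `p_value`.
#' @export
compare_sizes <- function(sizes_a, sizes_b) {
  if (length(sizes_a) == 0L || length(sizes_b) == 0L) {
    abort("both size lists must be non-empty")
  }
  gc <- group_compare(sizes_a, sizes_b)
  tibble(
    median_a = round(median(sizes_a), 2),
    median_b = round(median(sizes_b), 2),
    u = gc$u,
    p_value = gc$p_value
  )
}

#' Association of CNV carrier status with inclusions, per stratum
#'
#' Builds the stratified 2x2 tables via [build_table2()] and attaches the
#' full association statistics ([risk_ratios()], including the Fisher exact
#' p) to each stratum plus the pooled table. Strata with an empty exposure
#' arm are flagged and their estimates left undefined.
#'
#' @param cells Tibble with logical `has_cnv`, `has_inclusion` and the
#'   stratum columns.
#' @param strata Stratifying column names (default
#'   `c("disease", "cell_type")`).
#' @return Tibble: strata columns, `a`, `b`, `c`, `d`, `pct_incl_cnv`,
#'   `pct_incl_no_cnv`, `rr`, `rr_ci_low`, `rr_ci_high`, `or_`, `p_fisher`,
#'   `flags`, and an `assoc` list-column of `mosaic_assoc` objects.
#' @export
inclusion_association <- function(cells, strata = c("disease", "cell_type")) {
  tabs <- build_table2(cells, strata)
  res <- purrr::pmap(tabs[, c("a", "b", "c", "d")], function(a, b, c, d) {
    if (a + b == 0 || c + d == 0) {
      return(NULL)
    }
    risk_ratios(a, b, c, d)
  })
  tabs |>
    mutate(
      pct_incl_cnv = round(100 * .data$a / pmax(.data$a + .data$b, 1), 1),
      pct_incl_no_cnv = round(100 * .data$c / pmax(.data$c + .data$d, 1), 1),
      rr = purrr::map_dbl(res, ~ if (is.null(.x)) NA_real_ else .x$rr),
      rr_ci_low = purrr::map_dbl(res, ~ .x$rr_ci_low %||% NA_real_),
      rr_ci_high = purrr::map_dbl(res, ~ .x$rr_ci_high %||% NA_real_),
      or_ = purrr::map_dbl(res, ~ if (is.null(.x)) NA_real_ else .x$or),
      p_fisher = purrr::map_dbl(res,
                                ~ if (is.null(.x)) NA_real_ else .x$p_fisher),
      flags = purrr::map_chr(res, ~ if (is.null(.x)) "empty_arm" else
        paste(.x$flags, collapse = ",")),
      assoc = res
    )
}

#' Annotate calls with overlapping genes
#'
#' Lists every gene with at least 1 bp of overlap per call, and flags named
#' loci of interest (e.g. the SNCA locus on the synthetic genome).
#'
#' @param calls Call tibble.
#' @param gene_track Tibble with `chrom`, `start`, `end`, `name`.
#' @param loci_of_interest Character vector of gene names to flag
#'   (default `"SNCA"`).
#' @return `calls` with `genes` (list of character vectors) and
#'   `hits_locus_of_interest` (logical) columns.
#' @export
annotate_genes <- function(calls, gene_track, loci_of_interest = "SNCA") {
  assert_columns(gene_track, c("chrom", "start", "end", "name"),
                 "gene_track")
  genes <- vector("list", nrow(calls))
  if (nrow(calls) > 0L && nrow(gene_track) > 0L) {
    hits <- tbl_overlaps(calls, gene_track)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (i in seq_len(nrow(calls))) {
      genes[[i]] <- sort(unique(gene_track$name[sh[qh == i]]))
    }
  } else {
    genes <- replicate(nrow(calls), character(), simplify = FALSE)
  }
  mutate(
    calls,
    genes = genes,
    hits_locus_of_interest = purrr::map_lgl(
      genes, ~ any(.x %in% loci_of_interest)
    )
  )
}
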