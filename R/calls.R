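# From segments to filtered copy-number calls.

#' Count reads into grid bins
#'
#' A read is assigned to the bin containing its start coordinate (strand
#' ignored). Y-chromosome bins are counted but are never used for calling.
#'
#' @param reads Tibble of read intervals (`chrom`, `start`, optional `end`).
#' @param grid A [bin_grid()].
#' @return Integer vector of counts, one per grid bin.
#' @export
bin_reads <- function(reads, grid) {
  assert_columns(reads, c("chrom", "start"), "reads")
  unknown <- setdiff(unique(reads$chrom), unique(grid$chrom))
  if (length(unknown) > 0L) {
    abort(sprintf("reads on chromosome(s) not in the grid: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (nrow(reads) == 0L) {
    return(integer(nrow(grid)))
  }
  pts <- tibble(chrom = reads$chrom, start = reads$start,
                end = reads$start + 1)
  hits <- tbl_overlaps(pts, grid)
  tabulate(S4Vectors::subjectHits(hits), nbins = nrow(grid))
}

#' Extract raw copy-number calls from a segmented profile
#'
#' Every segment whose ploidy-scaled mean copy number exceeds the gain
#' cutoff becomes a gain call, and every one below the loss cutoff a loss;
#' segments between the cutoffs are consistent with diploid amplification
#' noise and are not called. Y segments are never emitted. A call spanning
#' an entire chromosome as a single segment is tagged as an
#' aneusomy candidate.
#'
#' @param segments Segment tibble from [segment_profile()].
#' @param ploidy Fitted ploidy scale.
#' @param cutoffs Named vector from [mixture_cutoffs()].
#' @param genome The [genome_model()].
#' @param cell_id Cell identifier attached to every call.
#' @return Tibble of calls: `cell_id`, `chrom`, `start`, `end`, `n_bins`,
#'   `cn_real`, `cn_int`, `kind`, `aneusomy_candidate`.
#' @export
extract_calls <- function(segments, ploidy, cutoffs, genome,
                          cell_id = "cell") {
  segs <- segments |>
    filter(.data$chrom != "chrY") |>
    mutate(cn_real = ploidy * .data$mean)
  calls <- segs |>
    filter(.data$cn_real > cutoffs[["gain"]] |
             .data$cn_real < cutoffs[["loss"]]) |>
    mutate(
      cell_id = cell_id,
      cn_int = round(.data$cn_real),
      kind = as.character(ifelse(.data$cn_real > cutoffs[["gain"]],
                                 "gain", "loss")),
      aneusomy_candidate = .data$start == 0 &
        .data$end == genome$chrom_lengths[.data$chrom]
    ) |>
    select("cell_id", "chrom", "start", "end", "first_bin", "last_bin",
           "n_bins", "cn_real", "cn_int", "kind", "aneusomy_candidate")
  calls
}

#' Filter raw calls by size, wave and recurrent-borderline rules
#'
#' Three removal rules, each recorded with a reason code:
#'
#' * `"a_min_bins"` — calls spanning fewer than 3 bins;
#' * `"b_wave"` — calls that look like a smooth coverage "wave" rather than
#'   a sharp step. The profile is re-binned at doubled bin size and the
#'   call's copy number re-estimated against its immediately flanking
#'   doubled-size bins: their excess over the cell's baseline is subtracted
#'   from the call CN, and the call is removed when the correction moves it
#'   toward the baseline by more than `max(wave_shift, wave_rel *
#'   |call excess|)` (defaults 0.15 and 0.25): an absolute floor for
#'   borderline calls plus a relative term so that strong calls need
#'   proportionally strong flank evidence. A sharp event steps straight
#'   back to baseline (flank excess ~ 0); a wave's shoulders carry much of
#'   its elevation, so it collapses;
#' * `"c_recurrent_centromeric"` — calls with borderline copy number (within
#'   `borderline` of a cutoff) overlapping a pericentromeric zone
#'   (centromere ± `pericentromere_pad`) and recurring at an overlapping
#'   locus in at least `recurrence` cells.
#'
#' @param calls Call tibble from [extract_calls()] (possibly several cells).
#' @param cell_values Named list (by `cell_id`) with elements `counts`
#'   (raw per-bin counts) and `ploidy`, used for the doubled-bin-size
#'   re-estimate.
#' @param grid,genome Bin grid and genome model.
#' @param cutoffs Named cutoff vector.
#' @param wave_shift,wave_rel,borderline,pericentromere_pad,recurrence
#'   Filter parameters (defaults 0.15, 0.25, 0.2, 2e6, 3).
#' @return `calls` with logical `kept` and character `reason` (`NA` when
#'   kept) columns appended.
#' @export
filter_calls <- function(calls, cell_values, grid, genome, cutoffs,
                         wave_shift = 0.15, wave_rel = 0.25,
                         borderline = 0.2, pericentromere_pad = 2e6,
                         recurrence = 3) {
  if (nrow(calls) == 0L) {
    return(mutate(calls, kept = logical(), reason = character()))
  }
  reason <- rep(NA_character_, nrow(calls))

  # (a) minimum size
  reason[calls$n_bins < 3] <- "a_min_bins"

  # (b) wave proxy: flanks on the per-bin profile, guarded at the boundary
  rebin <- lapply(cell_values, function(cv) {
    cn1 <- cv$ploidy * normalize_counts(cv$counts, grid, genome)
    auto <- grid$chrom %in% autosomes(genome)
    list(cn1 = cn1, chrom = grid$chrom, baseline = median(cn1[auto]))
  })
  for (i in which(is.na(reason))) {
    cv <- rebin[[calls$cell_id[i]]]
    if (is.null(cv)) next
    shift <- wave_cn_shift(calls[i, ], cv, calls[calls$cell_id ==
                                                   calls$cell_id[i], ])
    thr <- max(wave_shift, wave_rel * abs(calls$cn_real[i] - 2))
    if (!is.na(shift) && shift > thr) {
      reason[i] <- "b_wave"
    }
  }

  # (c) recurrent borderline pericentromeric calls
  near_cutoff <- pmin(abs(calls$cn_real - cutoffs[["gain"]]),
                      abs(calls$cn_real - cutoffs[["loss"]])) < borderline
  pericen <- rep(FALSE, nrow(calls))
  if (!is.null(genome$centromeres)) {
    zones <- genome$centromeres |>
      mutate(start = pmax(0, .data$start - pericentromere_pad),
             end = pmin(genome$chrom_lengths[.data$chrom],
                        .data$end + pericentromere_pad))
    pericen <- overlap_bp(calls[, c("chrom", "start", "end")], zones) > 0
  }
  n_cells_at <- recurrence_count(calls)
  cand <- is.na(reason) & near_cutoff & pericen & n_cells_at >= recurrence
  reason[cand] <- "c_recurrent_centromeric"

  mutate(calls, kept = is.na(reason), reason = reason)
}

# Number of distinct cells carrying a same-kind call overlapping each call.
recurrence_count <- function(calls) {
  out <- integer(nrow(calls))
  for (k in unique(calls$kind)) {
    idx <- which(calls$kind == k)
    gr <- as_granges(calls[idx, ])
    hits <- GenomicRanges::findOverlaps(gr, gr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    cells <- calls$cell_id[idx]
    out[idx] <- vapply(seq_along(idx), function(j) {
      length(unique(cells[sh[qh == j]]))
    }, integer(1))
  }
  out
}

# Re-bin a profile at doubled bin size: consecutive bin pairs within a
# chromosome are merged, counts summed, then normalised and ploidy-scaled.
# Returns a tibble grid2 with per-bin CN and the cell baseline.
rebin_profile <- function(counts, grid, genome, ploidy) {
  pair <- grid |>
    mutate(counts = counts) |>
    group_by(.data$chrom) |>
    mutate(pair = (row_number() - 1) %/% 2) |>
    group_by(.data$chrom, .data$pair) |>
    summarise(start = min(.data$start), end = max(.data$end),
              counts = sum(.data$counts), .groups = "drop") |>
    arrange(match(.data$chrom, unique(grid$chrom)), .data$start)
  auto <- pair$chrom %in% autosomes(genome)
  rate <- pair$counts / (pair$end - pair$start)
  v2 <- rate / mean(rate[auto])
  cn2 <- ploidy * v2
  list(grid2 = pair[, c("chrom", "start", "end")], cn2 = cn2,
       baseline = median(cn2[auto]))
}

# Flank-referenced wave shift for one call: how far the call CN moves
# toward the cell baseline once the flanking excess is subtracted. Each
# side's level is the median of the `flank_bins` nearest bins (robust to a
# bin of leftover event signal when a boundary is off by one), and the
# flank excess averages the two sides, with each side clamped at zero: a
# dip beyond one boundary (the opposite phase of an oscillation) is not
# evidence of sharpness and must not cancel an elevated shoulder. The
# per-side median absorbs a bin of leftover event signal when a boundary
# is off by one. Calls at a chromosome end use their single side.
wave_cn_shift <- function(call, rebinned, cell_calls, flank_bins = 3L) {
  on_chrom <- which(rebinned$chrom == call$chrom)
  lo <- min(on_chrom)
  hi <- max(on_chrom)
  left <- seq.int(max(lo, call$first_bin - flank_bins), call$first_bin - 1L)
  right <- seq.int(call$last_bin + 1L,
                   min(hi, call$last_bin + flank_bins))
  left <- left[left >= lo & left <= hi]
  right <- right[right >= lo & right <= hi]
  b <- rebinned$baseline
  dir <- sign(call$cn_real - b)
  side_excess <- function(idx) {
    if (length(idx) < 2L) NA_real_ else
      max(0, dir * (median(rebinned$cn1[idx]) - b))
  }
  sides <- c(side_excess(left), side_excess(right))
  if (all(is.na(sides))) {
    return(NA_real_)
  }
  flank_excess <- dir * mean(sides, na.rm = TRUE)
  cn_reest <- call$cn_real - flank_excess
  abs(call$cn_real - b) - abs(cn_reest - b)
}

#' Classify calls as pure aneusomy, polyploidy or sub-chromosomal
#'
#' A call spanning an entire chromosome at uniform integer copy number is a
#' pure aneusomy; cells whose fitted ploidy is at least 3.5 are labelled
#' polyploid; everything else is a sub-chromosomal CNV. Pure aneusomies and
#' polyploid cells are excluded from CNV composition tallies downstream.
#'
#' @param calls Call tibble (one or more cells).
#' @param ploidy_by_cell Named numeric vector of fitted ploidies.
#' @return `calls` with an `event_class` column.
#' @export
classify_chromosome_events <- function(calls, ploidy_by_cell) {
  if (nrow(calls) == 0L) {
    return(mutate(calls, event_class = character()))
  }
  mutate(
    calls,
    event_class = case_when(
      ploidy_by_cell[.data$cell_id] >= 3.5 ~ "polyploidy",
      .data$aneusomy_candidate ~ "pure_aneusomy",
      TRUE ~ "sub_chromosomal"
    )
  )
}

#' Run the full per-batch calling pipeline
#'
#' For each cell: normalise, segment, fit ploidy, compute QC. Segment copy
#' numbers of all QC-passing cells are pooled into the three-Gaussian
#' mixture, cutoffs derived, calls extracted per cell, classified, and
#' filtered with the batch-level rules. QC-failing cells yield no calls.
#'
#' One calibration guard applies to the cutoffs: the central component's sd
#' is floored at the sampling noise of a minimal (3-bin) call, estimated
#' from the within-segment per-bin residuals, because a cutoff tighter than
#' that noise cannot separate real events from fluctuation. On noisy data
#' the fitted sd exceeds the floor and the guard is inactive.
#'
#' @param profiles List of `cell_profile` objects (see [simulate_cell()]), or
#'   a cohort tibble from [simulate_cohort()].
#' @param sim A `sim_genome` (or any list with `genome` and `grid`).
#' @param alpha,min_bins,n_perm Segmentation parameters.
#' @param thresholds [qc_thresholds()].
#' @param two_tailed Mixture cutoff tail probability (default 0.01).
#' @param filter_params Named list overriding [filter_calls()] defaults.
#' @param seed Optional seed (segmentation permutations, EM restarts).
#' @return A list of class `cnv_batch`: `qc` (per-cell tibble), `segments`,
#'   `mixture`, `cutoffs`, `calls` (with `kept`, `reason`, `event_class`),
#'   `ploidy` (named vector).
#' @export
call_cells <- function(profiles, sim, alpha = 0.01, min_bins = 2,
                       n_perm = 1000, thresholds = qc_thresholds(),
                       two_tailed = 0.01, filter_params = list(),
                       seed = NULL) {
  if (is.data.frame(profiles)) {
    profiles <- profiles$profile
  }
  genome <- sim$genome
  grid <- sim$grid
  per_cell <- purrr::imap(profiles, function(p, i) {
    stopifnot(inherits(p, "cell_profile"))
    v <- normalize_counts(p$counts, grid, genome)
    segs <- segment_profile(v, grid, alpha = alpha, min_bins = min_bins,
                            n_perm = n_perm,
                            seed = child_seed(seed, paste0("seg", i)))
    ploidy <- fit_ploidy(segs, grid, genome)
    qc <- compute_qc(p$total_reads, v, segs, ploidy, grid, genome,
                     thresholds)
    list(profile = p, values = v, segments = segs, ploidy = ploidy, qc = qc)
  })
  ids <- vapply(per_cell, function(x) x$profile$cell_id, "")
  names(per_cell) <- ids

  qc <- bind_rows(lapply(per_cell, function(x) x$qc)) |>
    mutate(cell_id = ids, .before = 1)
  segments <- bind_rows(lapply(per_cell, function(x) {
    mutate(x$segments, cell_id = x$profile$cell_id,
           cn_real = x$ploidy * .data$mean)
  }))
  ploidy <- vapply(per_cell, function(x) x$ploidy, numeric(1))

  passing <- ids[qc$pass]
  empty_calls <- tibble(
    cell_id = character(), chrom = character(), start = double(),
    end = double(), first_bin = integer(), last_bin = integer(),
    n_bins = integer(), cn_real = double(), cn_int = double(),
    kind = character(), aneusomy_candidate = logical()
  )
  if (length(passing) == 0L) {
    calls <- empty_calls |>
      mutate(event_class = character(), kept = logical(),
             reason = character())
    return(structure(
      list(qc = qc, segments = segments, mixture = NULL,
           cutoffs = c(loss = NA_real_, gain = NA_real_), calls = calls,
           ploidy = ploidy),
      class = "cnv_batch"
    ))
  }
  pooled <- segments$cn_real[segments$cell_id %in% passing]
  mixture <- fit_cn_mixture(pooled, seed = child_seed(seed, "mixture"))
  # Calibration guard: the cutoff half-width cannot meaningfully be tighter
  # than the sampling noise of the smallest allowed call (3 bins, rule a),
  # so the central sd is floored at per-bin noise / sqrt(3). On noisy
  # batches the fitted sd is larger and the floor is inactive.
  sigma_bin <- median(vapply(per_cell[passing], function(x) {
    m <- per_bin_segment_means(x$segments, nrow(grid))
    ok <- grid$chrom %in% autosomes(genome) & !is.na(m)
    x$ploidy * sd((x$values - m)[ok])
  }, numeric(1)), na.rm = TRUE)
  central <- which.min(abs(mixture$means - 2))
  sd_floor <- sigma_bin / sqrt(3)
  if (is.finite(sd_floor) && mixture$sds[central] < sd_floor) {
    mixture$sds[central] <- sd_floor
    mixture$flags <- c(mixture$flags, "central_sd_floored")
  }
  cutoffs <- mixture_cutoffs(mixture, two_tailed)

  calls <- bind_rows(
    empty_calls,
    bind_rows(lapply(passing, function(id) {
      extract_calls(per_cell[[id]]$segments, per_cell[[id]]$ploidy, cutoffs,
                    genome, cell_id = id)
    }))
  )
  calls <- classify_chromosome_events(calls, ploidy)
  cell_values <- lapply(per_cell[passing], function(x) {
    list(counts = x$profile$counts, ploidy = x$ploidy)
  })
  calls <- do.call(filter_calls, c(
    list(calls = calls, cell_values = cell_values, grid = grid,
         genome = genome, cutoffs = cutoffs),
    filter_params
  ))

  structure(
    list(qc = qc, segments = segments, mixture = mixture, cutoffs = cutoffs,
         calls = calls, ploidy = ploidy),
    class = "cnv_batch"
  )
}

#' @export
print.cnv_batch <- function(x, ...) {
  cat(sprintf(
    "<cnv_batch> %d cells (%d passing QC), %d calls kept / %d raw\n",
    nrow(x$qc), sum(x$qc$pass), sum(x$calls$kept %||% FALSE),
    nrow(x$calls)
  ))
  cat(sprintf("  cutoffs: loss < %.2f, gain > %.2f\n",
              x$cutoffs[["loss"]], x$cutoffs[["gain"]]))
  invisible(x)
}
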