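# Boundary-feature enrichment: 1 Mb windows around call boundaries scored
# against the overlap distribution of random same-width regions.

#' Boundary windows around each call
#'
#' For every call, two windows of `width` bp centred on its boundaries
#' (`width/2` on either side), clipped at chromosome ends; clipped windows
#' are flagged.
#'
#' @param calls Call tibble.
#' @param genome The [genome_model()].
#' @param width Window width in bp (default 1 Mb).
#' @return Tibble with `call_idx` (row in `calls`), `cell_id` (when
#'   present), `side` (`"left"`/`"right"`), `chrom`, `start`, `end`,
#'   `clipped`.
#' @export
boundary_windows <- function(calls, genome, width = 1e6) {
  validate_intervals(calls, genome, "calls")
  half <- width / 2
  purrr::map_dfr(c(left = "left", right = "right"), function(side) {
    b <- if (side == "left") calls$start else calls$end
    s <- b - half
    e <- b + half
    len <- genome$chrom_lengths[calls$chrom]
    s_cl <- pmax(0, s)
    e_cl <- pmin(len, e)
    tibble(
      call_idx = seq_len(nrow(calls)),
      cell_id = if ("cell_id" %in% names(calls)) calls$cell_id else
        NA_character_,
      side = side,
      chrom = calls$chrom,
      start = unname(s_cl),
      end = unname(e_cl),
      clipped = s_cl != s | e_cl != e
    )
  })
}

#' Z-score of feature overlap against random regions
#'
#' For each window, `z = (observed - mean(null)) / sd(null)` where the null
#' is the base-pair overlap of a shared set of random same-width regions
#' with the feature track. `z > 1.96` is labelled enriched, `z < -1.96`
#' depleted (significance level 0.05). A degenerate null (sd 0) gives an
#' undefined z, status `"neutral"` and a flag.
#'
#' @param windows Tibble of windows (e.g. from [boundary_windows()]).
#' @param track Feature interval tibble.
#' @param null_regions Tibble of random regions from [random_regions()]
#'   (same width as the windows; 3000 by default upstream).
#' @return `windows` with `observed`, `null_mean`, `null_sd`, `z`, `status`
#'   and `degenerate_null` columns.
#' @export
enrichment_z <- function(windows, track, null_regions) {
  if (nrow(null_regions) == 0L) abort("`null_regions` must be non-empty")
  null_ov <- overlap_bp(null_regions, track)
  mu <- mean(null_ov)
  sdev <- sd(null_ov)
  obs <- overlap_bp(windows, track)
  if (sdev == 0) {
    warn("degenerate null overlap distribution (sd = 0); z undefined")
    return(mutate(windows, observed = obs, null_mean = mu, null_sd = 0,
                  z = NA_real_, status = "neutral", degenerate_null = TRUE))
  }
  z <- (obs - mu) / sdev
  mutate(
    windows,
    observed = obs,
    null_mean = mu,
    null_sd = sdev,
    z = z,
    status = case_when(z > 1.96 ~ "enriched",
                       z < -1.96 ~ "depleted",
                       TRUE ~ "neutral"),
    degenerate_null = FALSE
  )
}

#' Boundary-feature enrichment summary across calls
#'
#' Scores both boundary windows of every call against each feature track,
#' reports per-feature fractions of enriched boundaries by cell type (with a
#' Fisher exact comparison of the first two types), and lists calls enriched
#' at BOTH boundaries; when the segmental-duplication track carries
#' `pair_id`, both-boundary calls are annotated with the paralogous pairs
#' present at their two flanks.
#'
#' @param calls Call tibble (typically kept sub-chromosomal calls).
#' @param tracks Named list of feature tibbles.
#' @param cell_meta Tibble with `cell_id`, `cell_type`.
#' @param genome The [genome_model()].
#' @param n_null Number of random regions (default 3000).
#' @param width Window width (default 1 Mb).
#' @param seed Optional seed for the shared random-region draw.
#' @return List of class `cnv_enrichment`: `boundaries` (one row per
#'   boundary x feature), `fractions` (per feature x cell type, with
#'   `fisher_p` comparing the first two types), `both_boundaries` (calls
#'   enriched at both ends per feature, with `paralog_pairs`).
#' @export
enrichment_summary <- function(calls, tracks, cell_meta, genome,
                               n_null = 3000, width = 1e6, seed = NULL) {
  windows <- boundary_windows(calls, genome, width)
  null_regions <- random_regions(genome, n_null, width,
                                 seed = child_seed(seed, "null"))
  boundaries <- purrr::imap_dfr(tracks, function(track, feature) {
    mutate(enrichment_z(windows, track, null_regions), feature = feature,
           .before = 1)
  })
  with_type <- left_join(boundaries, cell_meta, by = "cell_id")
  fractions <- with_type |>
    group_by(.data$feature, .data$cell_type) |>
    summarise(
      n_boundaries = n(),
      n_enriched = sum(.data$status == "enriched"),
      pct_enriched = round(100 * mean(.data$status == "enriched"), 2),
      .groups = "drop"
    )
  fractions <- fractions |>
    group_by(.data$feature) |>
    mutate(fisher_p = {
      if (n() >= 2L) {
        fisher_exact(.data$n_enriched[1],
                     .data$n_boundaries[1] - .data$n_enriched[1],
                     .data$n_enriched[2],
                     .data$n_boundaries[2] - .data$n_enriched[2])
      } else {
        NA_real_
      }
    }) |>
    ungroup()

  both <- boundaries |>
    group_by(.data$feature, .data$call_idx) |>
    filter(all(c("left", "right") %in% .data$side[.data$status ==
                                                    "enriched"])) |>
    summarise(cell_id = .data$cell_id[1], .groups = "drop")
  if (nrow(both) > 0L) {
    both$paralog_pairs <- purrr::map2(both$feature, both$call_idx,
                                      function(f, i) {
      track <- tracks[[f]]
      if (is.null(track$pair_id)) {
        return(character())
      }
      w <- windows[windows$call_idx == i, ]
      at_side <- lapply(c("left", "right"), function(s) {
        ov <- overlap_bp(track, w[w$side == s, ])
        unique(track$pair_id[ov > 0])
      })
      sort(intersect(at_side[[1]], at_side[[2]]))
    })
  } else {
    both$paralog_pairs <- list()
  }

  structure(
    list(boundaries = boundaries, fractions = fractions,
         both_boundaries = both),
    class = "cnv_enrichment"
  )
}
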