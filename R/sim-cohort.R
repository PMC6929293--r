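#' Simulate a cohort of cells with known ground truth
#'
#' Draws cells of each type, plants copy-number events with per-type
#' gain:loss mixes, optionally plants a clonal event shared (with boundary
#' jitter) across several cells, assigns an SNCA-locus gain to a fraction of
#' cells, and draws inclusion status so that cells carrying an SNCA gain
#' have inclusion probability `p_incl_snca` and the rest `p_incl_base`
#' (target relative risk = the ratio of the two). Per-cell read profiles are
#' generated unless `simulate_reads = FALSE` (useful for label-level
#' statistics at scale).
#'
#' The defaults emulate the study conditions this generator is designed
#' around: roughly 30% of cells carry at least one sub-chromosomal CNV,
#' non-neurons carry almost exclusively gains (95%) against a near-even mix
#' in neurons (45%), inclusion probabilities 0.33 / 0.08 for SNCA-gain
#' carriers versus others, and a few percent of cells are tetraploid or
#' carry a whole-chromosome aneusomy.
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param n_by_type Named integer vector of cells per type, e.g.
#'   `c(neuron = 15, non_neuron = 15)`.
#' @param region Region label stored on every cell.
#' @param p_cnv Probability a cell carries at least one sub-chromosomal CNV.
#' @param n_events_range Integer range (min, max) of events for CNV-carrying
#'   cells.
#' @param gain_prob Named per-type probability that an event is a gain.
#' @param size_meanlog,size_sdlog Log-normal parameters of event size in bp;
#'   sizes are clamped to at least `min_bins` bins.
#' @param min_bins Minimum event size in bins (default 5).
#' @param p_snca_gain Probability a cell carries a gain spanning the SNCA
#'   locus (planted in addition to its other events).
#' @param p_incl_snca,p_incl_base Inclusion probabilities given SNCA-gain
#'   carrier status.
#' @param p_tetraploid,p_aneusomy Probabilities of a tetraploid cell or of a
#'   whole-chromosome aneusomy.
#' @param clone_spec Optional list `list(k =, chrom =, start =, end =, cn =,
#'   jitter =)`: plants the same event in `k` cells with boundaries jittered
#'   uniformly within `±jitter` bp.
#' @param noise A [noise_spec()] used for read simulation.
#' @param simulate_reads Generate per-cell read counts (default `TRUE`).
#' @param seed Optional seed.
#'
#' @return A tibble with one row per cell: `cell_id`, `cell_type`, `region`,
#'   `inclusion`, `has_snca_gain`, `base_ploidy`, `clone_member`, `truth`
#'   (list of [truth_profile()]) and `profile` (list of `cell_profile` or
#'   `NULL`).
#' @export
simulate_cohort <- function(sim,
                            n_by_type = c(neuron = 15, non_neuron = 15),
                            region = "SN",
                            p_cnv = 0.3,
                            n_events_range = c(1, 3),
                            gain_prob = c(neuron = 0.45, non_neuron = 0.95,
                                          olig2_pos = 1),
                            size_meanlog = log(5.5e6),
                            size_sdlog = 0.45,
                            min_bins = 5,
                            p_snca_gain = 0.05,
                            p_incl_snca = 0.33,
                            p_incl_base = 0.08,
                            p_tetraploid = 0.02,
                            p_aneusomy = 0.03,
                            clone_spec = NULL,
                            noise = noise_spec(),
                            simulate_reads = TRUE,
                            seed = NULL) {
  stopifnot(inherits(sim, "sim_genome"))
  types <- rep(names(n_by_type), n_by_type)
  probs <- c(p_cnv, gain_prob, p_snca_gain, p_incl_snca, p_incl_base,
             p_tetraploid, p_aneusomy)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must be in [0, 1]")
  n <- length(types)
  bw <- sim$bin_width
  with_seed_or_stream(seed, {
    clone_cells <- integer()
    if (!is.null(clone_spec)) {
      clone_cells <- sample(n, clone_spec$k)
    }
    rows <- purrr::map(seq_len(n), function(i) {
      type <- types[i]
      ploidy <- if (runif(1) < p_tetraploid) 4 else 2
      truth <- truth_profile(sprintf("cell%03d", i), cell_type = type,
                             region = region, base_ploidy = ploidy)
      if (i %in% clone_cells) {
        jit <- clone_spec$jitter %||% 0
        ev <- tibble(
          chrom = clone_spec$chrom,
          start = max(0, clone_spec$start + round(runif(1, -jit, jit))),
          end = clone_spec$end + round(runif(1, -jit, jit)),
          cn = clone_spec$cn %||% 3
        )
        truth <- plant_events(truth, ev, sim$genome)
      }
      has_snca <- runif(1) < p_snca_gain
      if (has_snca) {
        locus <- sim$snca_locus
        size <- max(min_bins * bw, round(rlnorm(1, size_meanlog, size_sdlog)))
        offset <- round(runif(1, 0, size - (locus$end - locus$start)))
        s <- max(0, locus$start - offset)
        e <- min(sim$genome$chrom_lengths[[locus$chrom]], s + size)
        truth <- tryCatch(
          plant_events(truth,
                       tibble(chrom = locus$chrom, start = s, end = e,
                              cn = ploidy + 1),
                       sim$genome),
          error = function(e) truth
        )
      }
      if (runif(1) < p_cnv) {
        k <- sample(seq(n_events_range[1], n_events_range[2]), 1)
        gains <- runif(k) < (gain_prob[[type]] %||% 0.5)
        sizes <- pmax(min_bins * bw, round(rlnorm(k, size_meanlog,
                                                  size_sdlog)))
        for (j in seq_len(k)) {
          cn_j <- if (gains[j]) ploidy + sample(1:2, 1, prob = c(0.8, 0.2))
                  else max(0, ploidy - 1)
          truth <- tryCatch(
            plant_random_events(truth, sim, n = 1, size = sizes[j],
                                cn = cn_j, placement = "random"),
            error = function(e) truth
          )
        }
      }
      if (runif(1) < p_aneusomy) {
        cn_a <- if (runif(1) < 0.5) ploidy + 1 else ploidy - 1
        truth <- tryCatch(
          plant_random_events(truth, sim, n = 1, cn = cn_a,
                              placement = "whole_chromosome"),
          error = function(e) truth
        )
      }
      # re-derive SNCA carrier status from the planted truth (an SNCA plant
      # can fail when it would overlap the clone event)
      carries_snca <- nrow(truth$events) > 0 &&
        any(truth$events$chrom == sim$snca_locus$chrom &
              truth$events$start < sim$snca_locus$end &
              truth$events$end > sim$snca_locus$start &
              truth$events$cn > truth$base_ploidy)
      truth$inclusion <- runif(1) <
        (if (carries_snca) p_incl_snca else p_incl_base)
      profile <- if (simulate_reads) {
        simulate_cell(truth, noise, sim)
      }
      list(
        cell_id = truth$cell_id,
        cell_type = type,
        inclusion = truth$inclusion,
        has_snca_gain = carries_snca,
        base_ploidy = ploidy,
        clone_member = i %in% clone_cells,
        truth = truth,
        profile = profile
      )
    })
    tibble(
      cell_id = vapply(rows, `[[`, "", "cell_id"),
      cell_type = vapply(rows, `[[`, "", "cell_type"),
      region = region,
      inclusion = vapply(rows, `[[`, NA, "inclusion"),
      has_snca_gain = vapply(rows, `[[`, NA, "has_snca_gain"),
      base_ploidy = vapply(rows, `[[`, numeric(1), "base_ploidy"),
      clone_member = vapply(rows, `[[`, NA, "clone_member"),
      truth = lapply(rows, `[[`, "truth"),
      profile = lapply(rows, function(r) r$profile)
    )
  })
}
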