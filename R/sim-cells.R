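# Ground-truth cell profiles and simulated single-cell read counts.
#
# The noise model is AR(1) log-normal amplification multiplied into Poisson
# read sampling: per bin i, counts ~ Poisson(depth_share_i * CN_i/ploidy *
# exp(g_i)) with g an AR(1) Gaussian of stationary sd `amp_sd` and
# coefficient `amp_corr`. amp_sd drives MAPD-style local noise; amp_corr
# close to 1 produces the low-frequency "waves" seen in uneven
# whole-genome amplification.

#' Amplification-noise specification
#'
#' @param depth Expected total reads per cell.
#' @param amp_sd Stationary standard deviation of the log-normal per-bin
#'   amplification factor.
#' @param amp_corr AR(1) coefficient in (-1, 1) for along-chromosome
#'   correlation of the amplification factor ("waves").
#' @param dropout_rate Fraction of bins with zero amplification.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(depth = 1e6, amp_sd = 0.1, amp_corr = 0,
                       dropout_rate = 0) {
  assert_number(depth, "depth", positive = TRUE)
  assert_number(amp_sd, "amp_sd")
  assert_number(amp_corr, "amp_corr")
  assert_number(dropout_rate, "dropout_rate")
  if (amp_sd < 0) abort("`amp_sd` must be >= 0")
  if (abs(amp_corr) >= 1) abort("`amp_corr` must be in (-1, 1)")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must be in [0, 1)")
  }
  structure(list(depth = depth, amp_sd = amp_sd, amp_corr = amp_corr,
                 dropout_rate = dropout_rate), class = "noise_spec")
}

# shared empty events tibble (constructed once; tibble() per cell is slow)
.empty_events <- NULL
empty_events <- function() {
  if (is.null(.empty_events)) {
    utils::assignInMyNamespace(".empty_events", tibble(
      chrom = character(), start = double(), end = double(), cn = double()
    ))
  }
  .empty_events
}

#' Create a ground-truth cell profile
#'
#' @param cell_id Cell identifier.
#' @param cell_type One of `"neuron"`, `"non_neuron"`, `"olig2_pos"`.
#' @param region Region label (free text, e.g. `"SN"`).
#' @param base_ploidy Baseline integer copy number of every autosome
#'   (2 for diploid, 4 for tetraploid cells).
#' @param inclusion Logical: does the cell carry an alpha-synuclein
#'   inclusion?
#' @return A list of class `truth_profile` with an empty `events` tibble
#'   (`chrom`, `start`, `end`, `cn`).
#' @export
truth_profile <- function(cell_id, cell_type = "neuron", region = "SN",
                          base_ploidy = 2, inclusion = FALSE) {
  if (!cell_type %in% c("neuron", "non_neuron", "olig2_pos")) {
    abort("unknown `cell_type`")
  }
  structure(
    list(
      cell_id = as.character(cell_id),
      cell_type = cell_type,
      region = region,
      base_ploidy = base_ploidy,
      inclusion = isTRUE(inclusion),
      events = empty_events()
    ),
    class = "truth_profile"
  )
}

#' Plant copy-number events into a truth profile
#'
#' Appends events, refusing overlaps with already-planted events. Events are
#' given either explicitly (`events` tibble with `chrom`, `start`, `end`,
#' `cn`) or drawn via [plant_random_events()].
#'
#' @param truth A [truth_profile()].
#' @param events Tibble of events with columns `chrom`, `start`, `end`, `cn`
#'   (absolute integer copy number).
#' @param genome Optional [genome_model()] to validate against.
#' @return The updated `truth_profile`.
#' @export
plant_events <- function(truth, events, genome = NULL) {
  stopifnot(inherits(truth, "truth_profile"))
  events <- as_tibble(events)
  assert_columns(events, c("chrom", "start", "end", "cn"), "events")
  validate_intervals(events, genome, "events")
  if (any(events$cn < 0)) abort("copy numbers must be >= 0")
  all_ev <- bind_rows(truth$events, events)
  ov <- GenomicRanges::findOverlaps(as_granges(all_ev),
                                    drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov) > 0L) {
    abort("planted events must not overlap within a cell")
  }
  truth$events <- arrange(all_ev, .data$chrom, .data$start)
  truth
}

#' Plant randomly-placed events
#'
#' Draws `n` events of the given sizes and copy numbers at random positions.
#' Placement `"random"` is uniform over autosomes; `"sd_flanked"` places both
#' boundaries inside the segmental-duplication pair flanking a planted
#' hotspot (emulating CNVs arising by recombination between the pair);
#' `"whole_chromosome"` spans an entire autosome (a pure aneusomy when it is
#' the cell's only event on that chromosome). Bounded retries; errors when
#' placement is infeasible.
#'
#' @param truth A [truth_profile()].
#' @param sim A `sim_genome` (for the genome, grid and hotspot tracks).
#' @param n Number of events.
#' @param size Event size in bp (vector recycled over events; ignored for
#'   `"whole_chromosome"`).
#' @param cn Absolute integer copy number (recycled).
#' @param placement `"random"`, `"sd_flanked"` or `"whole_chromosome"`.
#' @param seed Optional seed.
#' @return The updated `truth_profile`.
#' @export
plant_random_events <- function(truth, sim, n = 1, size = 2.5e6, cn = 3,
                                placement = c("random", "sd_flanked",
                                              "whole_chromosome"),
                                seed = NULL) {
  placement <- match.arg(placement)
  stopifnot(inherits(sim, "sim_genome"))
  genome <- sim$genome
  auto <- autosomes(genome)
  size <- rep_len(size, n)
  cn <- rep_len(cn, n)
  bw <- sim$bin_width
  with_seed_or_stream(seed, {
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        ev <- switch(placement,
          random = {
            space <- genome$chrom_lengths[auto] - size[i]
            space <- space[space > 0]
            if (length(space) == 0L) abort("event larger than every autosome")
            chrom <- sample(names(space), 1, prob = space)
            s <- floor(runif(1, 0, space[chrom]) / bw) * bw
            tibble(chrom = chrom, start = s, end = s + size[i], cn = cn[i])
          },
          sd_flanked = {
            if (nrow(sim$hotspots) == 0L) {
              abort("no planted hotspots available for SD-flanked placement")
            }
            h <- sim$hotspots[sample(nrow(sim$hotspots), 1), ]
            # boundaries jittered within the 100 kb flanking SDs
            tibble(chrom = h$chrom,
                   start = h$start + sample(c(-1, 0, 1), 1) * bw / 10,
                   end = h$end + sample(c(-1, 0, 1), 1) * bw / 10,
                   cn = cn[i])
          },
          whole_chromosome = {
            chrom <- sample(auto, 1)
            tibble(chrom = chrom, start = 0,
                   end = unname(genome$chrom_lengths[chrom]), cn = cn[i])
          }
        )
        ok <- tryCatch({
          truth <- plant_events(truth, ev, genome)
          TRUE
        }, error = function(e) FALSE)
        if (ok) {
          placed <- TRUE
          break
        }
      }
      if (!placed) abort("infeasible event placement after bounded retries")
    }
    truth
  })
}

# Integer copy-number vector over the grid implied by a truth profile.
# Y is 0 (the synthetic cells are XX); X follows base ploidy.
truth_cn_vector <- function(truth, sim) {
  grid <- sim$grid
  cn <- rep(truth$base_ploidy, nrow(grid))
  cn[grid$chrom == "chrY"] <- 0
  if (nrow(truth$events) > 0L) {
    hits <- tbl_overlaps(grid, truth$events)
    # a bin takes the CN of the event containing its start coordinate
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    contains_start <- grid$start[qh] >= truth$events$start[sh] &
      grid$start[qh] < truth$events$end[sh]
    cn[qh[contains_start]] <- truth$events$cn[sh[contains_start]]
  }
  cn
}

#' Simulate one cell's binned read counts
#'
#' Applies the AR(1) log-normal x Poisson noise model (see [noise_spec()]) to
#' the truth profile's copy-number vector.
#'
#' @param truth A [truth_profile()].
#' @param noise A [noise_spec()].
#' @param sim A `sim_genome`.
#' @param seed Optional seed.
#' @return A list of class `cell_profile`: `cell_id`, metadata, `counts`
#'   (one per grid bin) and `total_reads`.
#' @export
simulate_cell <- function(truth, noise, sim, seed = NULL) {
  stopifnot(inherits(truth, "truth_profile"), inherits(noise, "noise_spec"),
            inherits(sim, "sim_genome"))
  grid <- sim$grid
  cn <- truth_cn_vector(truth, sim)
  with_seed_or_stream(seed, {
    g <- ar1_field(grid$chrom, noise$amp_sd, noise$amp_corr)
    amp <- exp(g)
    if (noise$dropout_rate > 0) {
      amp[runif(length(amp)) < noise$dropout_rate] <- 0
    }
    w <- (cn / truth$base_ploidy) * amp * (grid$end - grid$start)
    lambda <- noise$depth * w / sum(w)
    counts <- rpois(length(lambda), lambda)
    structure(
      list(
        cell_id = truth$cell_id,
        cell_type = truth$cell_type,
        region = truth$region,
        inclusion = truth$inclusion,
        counts = counts,
        total_reads = sum(counts)
      ),
      class = "cell_profile"
    )
  })
}

# Stationary AR(1) Gaussian field, restarted at each chromosome boundary.
ar1_field <- function(chrom, sd, phi) {
  n <- length(chrom)
  if (sd == 0) {
    return(numeric(n))
  }
  if (phi == 0) {
    return(rnorm(n, 0, sd))
  }
  eps <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  out <- numeric(n)
  new_chrom <- c(TRUE, chrom[-1] != chrom[-n])
  for (i in seq_len(n)) {
    out[i] <- if (new_chrom[i]) rnorm(1, 0, sd) else phi * out[i - 1] + eps[i]
  }
  out
}
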