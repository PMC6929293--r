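# Shared fixtures, all built in code.

tiny_genome <- function() {
  genome_model(
    c(chr1 = 1e7, chr2 = 8e6, chrX = 5e6, chrY = 2e6),
    centromeres = tibble::tibble(
      chrom = c("chr1", "chr2"), start = c(4e6, 3e6), end = c(4.5e6, 3.5e6)
    )
  )
}

# a compact simulated genome reused across tests (memoised per session)
.small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.small_sim_cache$sim)) {
    .small_sim_cache$sim <- simulate_genome(
      autosome_lengths = stats::setNames(rep(5e7, 4), paste0("chr", 1:4)),
      sex_lengths = c(chrX = 1e7, chrY = 5e6),
      n_hotspots = 1, seed = 501
    )
  }
  .small_sim_cache$sim
}

# Random same-kind decoy calls with a minimum pairwise boundary separation.
# Decoys model private (non-clonal) CNVs: ground truth can only label them
# non-clonal if no two of them satisfy the clonality criterion, hence the
# separation constraint (2.5x the clone tolerance by default).
make_decoy_calls <- function(genome, n, min_sep = 2.5e6,
                             size_range = c(2e6, 3e7), kind = "gain",
                             avoid = NULL) {
  auto <- setdiff(names(genome$chrom_lengths), genome$sex_chroms)
  out <- if (is.null(avoid)) {
    tibble::tibble(cell_id = character(), chrom = character(),
                   start = double(), end = double(), kind = character())
  } else {
    avoid
  }
  n_avoid <- nrow(out)
  tries <- 0L
  while (nrow(out) < n + n_avoid && tries < 2000L) {
    tries <- tries + 1L
    size <- stats::runif(1, size_range[1], size_range[2])
    space <- genome$chrom_lengths[auto] - size
    space <- space[space > 0]
    chrom <- sample(names(space), 1, prob = space)
    start <- floor(stats::runif(1, 0, space[chrom]))
    cand <- tibble::tibble(
      cell_id = sprintf("decoy%03d", nrow(out) + 1L),
      chrom = chrom, start = start, end = start + size, kind = kind
    )
    same <- out[out$chrom == chrom, ]
    ok <- nrow(same) == 0L ||
      all(abs(same$start - cand$start) > min_sep |
            abs(same$end - cand$end) > min_sep)
    if (ok) out <- dplyr::bind_rows(out, cand)
  }
  stopifnot(nrow(out) == n + n_avoid)
  out[seq(n_avoid + 1L, n + n_avoid), ]
}

# brute-force per-base overlap oracle on small coordinates
per_base_overlap <- function(window, track) {
  covered <- rep(FALSE, window$end - window$start)
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] != window$chrom) next
    s <- max(track$start[i], window$start)
    e <- min(track$end[i], window$end)
    if (s < e) covered[(s - window$start + 1):(e - window$start)] <- TRUE
  }
  sum(covered)
}
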