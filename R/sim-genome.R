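# Synthetic genome, bin grid and feature tracks with known ground truth.
#
# The default genome is a compact 1 Gb stand-in for a human reference: 20
# autosomes with decreasing lengths (70..25 Mb), a 40 Mb X and a 10 Mb Y,
# which at the default 250 kb bin width gives exactly 4000 bins. A named
# SNCA locus is placed on chr4 so locus-aware association tests can run.

default_autosome_lengths <- function() {
  mb <- c(70, 68, 65, 63, 61, 58, 56, 54, 50, 49,
          46, 44, 42, 38, 37, 35, 32, 30, 27, 25)
  setNames(mb * 1e6, paste0("chr", seq_along(mb)))
}

#' Simulate a genome with feature tracks
#'
#' Builds a [genome_model()], its [bin_grid()], and synthetic feature tracks:
#' telomeres (terminal windows of each chromosome), fragile sites, segmental
#' duplications placed in paralogous pairs, and a sparse gene track including
#' a named `SNCA` locus. Optionally plants CNV "hotspots": loci flanked on
#' both sides by a paralogous segmental-duplication pair, emulating regions
#' where non-allelic homologous recombination between the pair generates
#' recurrent CNVs.
#'
#' @param autosome_lengths Named vector of autosome lengths in bp (default: a
#'   20-autosome, 950 Mb layout).
#' @param sex_lengths Named vector for the sex chromosomes (default 40 Mb X,
#'   10 Mb Y).
#' @param bin_width Bin width in bp (default 250 kb).
#' @param feature_density List with per-Mb element densities `segdup` and
#'   `fragile_site`, and `telomere_mb`, the terminal window length defining
#'   the telomere track (default 1 Mb per chromosome end).
#' @param n_hotspots Number of SD-flanked CNV hotspots to plant (default 2).
#' @param centromere_width Width of the centromere interval placed at 40% of
#'   each chromosome (default 2 Mb).
#' @param seed Optional integer seed.
#'
#' @return A list of class `sim_genome` with elements `genome`, `grid`,
#'   `tracks` (named list of interval tibbles; `segdup` carries `pair_id`),
#'   `genes` (gene track with a `name` column, including `SNCA`),
#'   `snca_locus` (one-row tibble) and `hotspots`.
#' @export
simulate_genome <- function(autosome_lengths = default_autosome_lengths(),
                            sex_lengths = c(chrX = 4e7, chrY = 1e7),
                            bin_width = 250e3,
                            feature_density = list(segdup = 0.02,
                                                   fragile_site = 0.005,
                                                   telomere_mb = 1),
                            n_hotspots = 2,
                            centromere_width = 2e6,
                            seed = NULL) {
  lengths <- c(autosome_lengths, sex_lengths)
  cen_start <- floor(lengths * 0.4 / 1e5) * 1e5
  centromeres <- tibble(
    chrom = normalize_chrom(names(lengths), quiet = TRUE),
    start = unname(cen_start),
    end = unname(pmin(cen_start + centromere_width, lengths))
  )
  genome <- genome_model(lengths, centromeres = centromeres,
                         sex_chroms = names(sex_lengths))
  grid <- bin_grid(genome, bin_width)
  auto <- autosomes(genome)

  with_seed_or_stream(seed, {
    tel_mb <- (feature_density$telomere_mb %||% 1) * 1e6
    telomere <- bind_rows(
      tibble(chrom = names(genome$chrom_lengths), start = 0,
             end = pmin(tel_mb, unname(genome$chrom_lengths))),
      tibble(chrom = names(genome$chrom_lengths),
             start = pmax(0, unname(genome$chrom_lengths) - tel_mb),
             end = unname(genome$chrom_lengths))
    ) |> arrange(.data$chrom, .data$start)

    fragile_site <- place_features(
      genome, auto,
      n = round((feature_density$fragile_site %||% 0) *
                  sum(genome$chrom_lengths[auto]) / 1e6),
      width = 1e6
    )

    # random paralogous SD pairs: two 50 kb elements sharing a pair_id
    n_sd_pairs <- round((feature_density$segdup %||% 0) *
                          sum(genome$chrom_lengths[auto]) / 1e6 / 2)
    segdup <- place_features(genome, auto, n = 2 * n_sd_pairs, width = 5e4)
    if (nrow(segdup) > 0L) {
      segdup$pair_id <- paste0("sd_pair", rep(seq_len(n_sd_pairs), each = 2))
    } else {
      segdup$pair_id <- character()
    }

    # SD-flanked CNV hotspots: a 3 Mb locus with a 100 kb paralogous SD
    # straddling each edge
    hotspots <- tibble(chrom = character(), start = double(), end = double())
    if (n_hotspots > 0) {
      hs_chroms <- sample(auto[seq_len(min(n_hotspots, length(auto)))])
      hotspots <- purrr::map_dfr(seq_len(n_hotspots), function(i) {
        chrom <- hs_chroms[((i - 1) %% length(hs_chroms)) + 1]
        len <- genome$chrom_lengths[[chrom]]
        s <- floor(runif(1, 3e6, len * 0.35 - 4e6) / 1e5) * 1e5
        tibble(chrom = chrom, start = s, end = s + 3e6,
               hotspot_id = paste0("hotspot", i))
      })
      hs_sd <- purrr::map_dfr(seq_len(nrow(hotspots)), function(i) {
        h <- hotspots[i, ]
        tibble(
          chrom = h$chrom,
          start = c(h$start - 5e4, h$end - 5e4),
          end = c(h$start + 5e4, h$end + 5e4),
          pair_id = paste0(h$hotspot_id, "_sd")
        )
      })
      segdup <- bind_rows(segdup, hs_sd) |> arrange(.data$chrom, .data$start)
    }

    # sparse gene track (10 kb genes) plus the named SNCA locus
    genes <- place_features(genome, auto, n = 200, width = 1e4)
    genes$name <- sprintf("GENE%03d", seq_len(nrow(genes)))
    snca <- tibble(chrom = "chr4", start = 3e7, end = 3e7 + 1e5,
                   name = "SNCA")
    genes <- bind_rows(genes, snca) |> arrange(.data$chrom, .data$start)

    structure(
      list(
        genome = genome,
        grid = grid,
        tracks = list(segdup = segdup, fragile_site = fragile_site,
                      telomere = telomere),
        genes = genes,
        snca_locus = snca,
        hotspots = hotspots,
        bin_width = bin_width
      ),
      class = "sim_genome"
    )
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf(
    "<sim_genome> %d chromosomes, %d bins of %g kb, %d feature tracks\n",
    length(x$genome$chrom_lengths), nrow(x$grid), x$bin_width / 1e3,
    length(x$tracks)
  ))
  invisible(x)
}

# Place n non-overlapping features of fixed width uniformly on the given
# chromosomes. Candidates are oversampled and thinned greedily; bounded
# rounds, erroring when the requested density is infeasible.
place_features <- function(genome, chroms, n, width, max_tries = 50L) {
  if (n <= 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  sub <- genome$chrom_lengths[chroms]
  if (n * width > 0.5 * sum(sub)) {
    abort("feature density too high to place without overlap")
  }
  space <- sub - width
  kept <- tibble(chrom = character(), start = double(), end = double())
  for (try in seq_len(max_tries)) {
    need <- n - nrow(kept)
    if (need <= 0L) break
    m <- 2L * need
    chrom <- sample(names(sub), m, replace = TRUE, prob = pmax(space, 1))
    start <- floor(runif(m, 0, space[chrom]))
    cand <- bind_rows(kept,
                      tibble(chrom = chrom, start = start,
                             end = start + width)) |>
      arrange(.data$chrom, .data$start)
    gap <- c(TRUE, cand$chrom[-1] != cand$chrom[-nrow(cand)] |
               cand$start[-1] >= cand$end[-nrow(cand)])
    kept <- head(cand[gap, ], n)
  }
  if (nrow(kept) < n) {
    abort("could not place features without overlap after bounded retries")
  }
  arrange(kept, .data$chrom, .data$start)
}
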