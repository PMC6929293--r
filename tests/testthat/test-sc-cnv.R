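# Normalisation, segmentation, ploidy, QC, mixture model and call filtering.

test_that("bin_reads assigns reads to the bin containing their start", {
  g <- tiny_genome()
  grid <- bin_grid(g, 250e3)
  expect_equal(bin_reads(tibble::tibble(chrom = character(),
                                        start = double()), grid),
               integer(nrow(grid)))
  reads <- tibble::tibble(chrom = "chr1", start = c(10, 250010, 250020))
  counts <- bin_reads(reads, grid)
  expect_equal(counts[1:2], c(1L, 2L))
  expect_error(bin_reads(tibble::tibble(chrom = "chrZ", start = 1), grid),
               "chrZ")

  set.seed(21)
  n <- 1e5
  reads <- tibble::tibble(
    chrom = sample(names(g$chrom_lengths), n, replace = TRUE)
  )
  reads$start <- floor(runif(n, 0, g$chrom_lengths[reads$chrom]))
  counts <- bin_reads(reads, grid)
  # brute-force tally oracle
  oracle <- integer(nrow(grid))
  idx <- match(reads$chrom, grid$chrom) # first bin of each chromosome
  off <- floor(reads$start / 250e3)
  tal <- table(idx + off)
  oracle[as.integer(names(tal))] <- as.integer(tal)
  expect_equal(counts, oracle)
})

test_that("normalize_counts scales the autosomal mean to exactly 1", {
  g <- tiny_genome()
  grid <- bin_grid(g, 250e3)
  uniform <- rep(100, nrow(grid))
  v <- normalize_counts(uniform, grid, g)
  expect_true(all(abs(v - 1) < 1e-12))
  auto <- grid$chrom %in% c("chr1", "chr2")
  set.seed(2)
  counts <- rpois(nrow(grid), 200)
  v2 <- normalize_counts(counts, grid, g)
  rate <- counts / (grid$end - grid$start)
  expect_equal(mean(v2[auto]), 1, tolerance = 1e-12)
  expect_error(normalize_counts(numeric(nrow(grid)), grid, g), "no autosomal")
})

test_that("flat noiseless profiles yield one segment per chromosome", {
  g <- tiny_genome()
  grid <- bin_grid(g, 250e3)
  segs <- segment_profile(rep(1, nrow(grid)), grid, seed = 1)
  expect_equal(nrow(segs), sum(unique(grid$chrom) != "chrY"))
  expect_true(all(segs$mean == 1))
})

test_that("scan maximum equals exhaustive single-segment search (<=30 bins)", {
  exhaustive <- function(x, min_bins) {
    n <- length(x)
    best <- -Inf
    for (L in min_bins:(n - min_bins)) {
      for (s in 0:(n - L)) {
        inside <- x[(s + 1):(s + L)]
        outside <- x[-((s + 1):(s + L))]
        sp2 <- (sum((inside - mean(inside))^2) +
                  sum((outside - mean(outside))^2)) / (n - 2)
        se <- sqrt(sp2 * (1 / L + 1 / (n - L)))
        t <- abs(mean(inside) - mean(outside)) / se
        if (is.finite(t) && t > best) best <- t
      }
    }
    best
  }
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(sample(10:30, 1)) + rep(c(0, 0.8, 0), c(4, 5, 6))[1]
    got <- mosaicnv:::scan_max(x, 2)
    expect_equal(got$stat, exhaustive(x, 2), tolerance = 1e-10)
  }
})

test_that("a planted step is recovered within one bin", {
  g <- genome_model(c(chr1 = 5e7), sex_chroms = character())
  grid <- bin_grid(g, 250e3) # 200 bins
  hits <- 0L
  n_rep <- 100L
  for (i in seq_len(n_rep)) {
    set.seed(1000 + i)
    x <- rnorm(200, 1, 0.1)
    x[96:105] <- x[96:105] + 0.5
    segs <- segment_profile(x, grid, seed = 2000 + i)
    ev <- segs[which.max(segs$mean), ]
    ok <- abs(ev$first_bin - 96) <= 1 && abs(ev$last_bin - 105) <= 1
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("fit_ploidy recovers the integer scale", {
  g <- tiny_genome()
  grid <- bin_grid(g, 250e3)
  flat <- segment_profile(rep(1, nrow(grid)), grid, seed = 3)
  expect_equal(fit_ploidy(flat, grid, g), 2)

  # tetraploid with a lost chromosome: relative levels 1 and 0.75
  v <- rep(1, nrow(grid))
  v[grid$chrom == "chr2"] <- 0.75
  segs <- segment_profile(v, grid, seed = 4)
  expect_equal(fit_ploidy(segs, grid, g), 4)
})

test_that("ploidy recovery tolerates amplification noise", {
  sim <- small_sim()
  ok <- 0L
  for (i in 1:10) {
    tr <- truth_profile(paste0("pl", i))
    tr <- plant_random_events(tr, sim, n = 2, size = 5e6, cn = c(3, 1),
                              seed = 300 + i)
    p <- simulate_cell(tr, noise_spec(amp_sd = 0.15), sim, seed = 400 + i)
    v <- normalize_counts(p$counts, sim$grid, sim$genome)
    segs <- segment_profile(v, sim$grid, seed = 500 + i)
    pl <- fit_ploidy(segs, sim$grid, sim$genome)
    ok <- ok + (abs(pl - 2) <= 0.05)
  }
  expect_gte(ok, 9L)
})

test_that("compute_qc reproduces hand-computed MAPD and gates", {
  g <- genome_model(c(chr1 = 1e6), sex_chroms = character())
  grid <- bin_grid(g, 250e3)
  values <- c(2.0, 2.1, 1.9, 2.0) / 2 # per-bin CN (2.0,2.1,1.9,2.0) at c=2
  segs <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6,
                         first_bin = 1L, last_bin = 4L, n_bins = 4L,
                         mean = 1)
  qc <- compute_qc(1e6, values, segs, 2, grid, g)
  expect_equal(qc$mapd, 0.1) # median of (0.1, 0.2, 0.1)
  expect_equal(qc$confidence, 1)
  expect_true(qc$pass)

  # noiseless integer profile: MAPD 0, confidence 1
  qc0 <- compute_qc(1e6, rep(1, 4), segs, 2, grid, g)
  expect_equal(qc0$mapd, 0)
  expect_equal(qc0$confidence, 1)

  # one read below the threshold fails with reason "reads"
  qc_r <- compute_qc(799999, rep(1, 4), segs, 2, grid, g)
  expect_false(qc_r$pass)
  expect_equal(qc_r$fail_reasons, "reads")
  expect_true(compute_qc(800001, rep(1, 4), segs, 2, grid, g)$pass)
})

test_that("MAPD increases monotonically with amplification noise", {
  sim <- small_sim()
  tr <- truth_profile("qcmono")
  mapds <- sapply(c(0.05, 0.1, 0.2, 0.3), function(s) {
    p <- simulate_cell(tr, noise_spec(amp_sd = s), sim, seed = 600 + s * 100)
    v <- normalize_counts(p$counts, sim$grid, sim$genome)
    segs <- tibble::tibble(chrom = "chr1", start = 0, end = 5e7,
                           first_bin = 1L, last_bin = 200L, n_bins = 200L,
                           mean = 1)
    compute_qc(p$total_reads, v, segs, 2, sim$grid, sim$genome)$mapd
  })
  expect_true(all(diff(mapds) > 0))
})

test_that("mixture EM recovers parameters and keeps likelihood monotone", {
  set.seed(13)
  cns <- c(rnorm(200, 1, 0.1), rnorm(1600, 2, 0.2), rnorm(200, 3, 0.15))
  m <- fit_cn_mixture(cns, seed = 14)
  ord <- order(m$means)
  expect_equal(m$means[ord], c(1, 2, 3), tolerance = 0.05)
  expect_equal(m$sds[ord], c(0.1, 0.2, 0.15), tolerance = 0.03)
  expect_equal(m$weights[ord], c(0.1, 0.8, 0.1), tolerance = 0.03)
  expect_true(all(diff(m$loglik_trace) > -1e-9))
})

test_that("mixture agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(15)
  cns <- c(rnorm(150, 1, 0.12), rnorm(1200, 2, 0.2), rnorm(150, 3, 0.15))
  m <- fit_cn_mixture(cns, seed = 16)
  ref <- mclust::Mclust(cns, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(m$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
})

test_that("degenerate mixtures fall back to a robust central estimate", {
  m <- fit_cn_mixture(rep(2, 500), seed = 17)
  expect_true(m$degenerate)
  cuts <- mixture_cutoffs(m)
  expect_equal(unname(cuts[["loss"]] + cuts[["gain"]]), 4, tolerance = 1e-6)
  expect_true(fit_cn_mixture(rnorm(10, 2, 0.1))$degenerate)
})

test_that("mixture_cutoffs inverts the 1% two-tailed rule", {
  m <- cnv_mixture(c(0.1, 0.8, 0.1), c(1, 2, 3),
                   c(0.1, 0.55 / qnorm(0.995), 0.15))
  cuts <- mixture_cutoffs(m)
  expect_equal(round(unname(cuts), 2), c(1.45, 2.55))
  expect_equal(unname(cuts[["loss"]] + cuts[["gain"]]), 4)

  tiny <- cnv_mixture(c(0.1, 0.8, 0.1), c(1, 2, 3), c(0.1, 1e-9, 0.15))
  expect_equal(unname(mixture_cutoffs(tiny)), c(2, 2), tolerance = 1e-6)

  # width grows with sigma and with smaller tail probability
  wide <- cnv_mixture(c(0.1, 0.8, 0.1), c(1, 2, 3), c(0.1, 0.3, 0.15))
  expect_gt(mixture_cutoffs(wide)[["gain"]], cuts[["gain"]])
  stricter <- mixture_cutoffs(m, two_tailed = 0.001)
  expect_gt(stricter[["gain"]], cuts[["gain"]])
})

test_that("extract_calls applies cutoffs at the boundary and skips Y", {
  g <- tiny_genome()
  cuts <- c(loss = 1.45, gain = 2.55)
  segs <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chrY"),
    start = c(0, 5e6, 0, 4e6, 0),
    end = c(5e6, 1e7, 4e6, 8e6, 2e6),
    first_bin = c(1L, 21L, 41L, 57L, 93L),
    last_bin = c(20L, 40L, 56L, 72L, 100L),
    n_bins = c(20L, 20L, 16L, 16L, 8L),
    mean = c(2.6, 1.50, 1.44, 2.0, 9) / 2
  )
  calls <- extract_calls(segs, 2, cuts, g, cell_id = "c")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$kind, c("gain", "loss"))
  expect_equal(calls$cn_real, c(2.6, 1.44))
  expect_false(any(calls$chrom == "chrY"))
})

test_that("filter rules: size, pericentromeric recurrence, wave basics", {
  sim <- small_sim()
  g <- sim$genome
  cuts <- c(loss = 1.45, gain = 2.55)
  base_call <- function(cell, chrom, start, end, cn, nb) {
    fb <- sim$grid$bin[sim$grid$chrom == chrom & sim$grid$start == start]
    tibble::tibble(cell_id = cell, chrom = chrom, start = start, end = end,
                   first_bin = fb, last_bin = fb + nb - 1L, n_bins = nb,
                   cn_real = cn, cn_int = round(cn),
                   kind = ifelse(cn > 2, "gain", "loss"),
                   aneusomy_candidate = FALSE)
  }
  # flat profiles for every involved cell
  flat <- lapply(1:4, function(i) list(counts = rep(250, 4000)[1:860] * 0 +
                                         250, ploidy = 2))
  names(flat) <- paste0("c", 1:4)

  # (a) a 2-bin call is removed
  calls_a <- base_call("c1", "chr1", 1e7, 1.05e7, 2.8, 2L)
  out_a <- filter_calls(calls_a, flat["c1"], sim$grid, g, cuts)
  expect_false(out_a$kept)
  expect_equal(out_a$reason, "a_min_bins")

  # (c) borderline pericentromeric call present in 4 cells is removed;
  # the same call far from the centromere is kept
  cen <- g$centromeres[g$centromeres$chrom == "chr1", ]
  near <- floor((cen$start - 1e6) / 250e3) * 250e3
  calls_c <- dplyr::bind_rows(lapply(paste0("c", 1:4), function(id) {
    base_call(id, "chr1", near, near + 1.25e6, 2.57, 5L)
  }))
  far <- base_call("c1", "chr2", 1e6, 2.25e6, 2.57, 5L)
  out_c <- filter_calls(dplyr::bind_rows(calls_c, far), flat, sim$grid, g,
                        cuts)
  expect_true(all(out_c$reason[1:4] == "c_recurrent_centromeric"))
  expect_true(out_c$kept[5])

  # clearly non-borderline recurrent pericentromeric calls are kept
  calls_c2 <- dplyr::mutate(calls_c, cn_real = 3.2, cn_int = 3)
  out_c2 <- filter_calls(calls_c2, flat, sim$grid, g, cuts)
  expect_true(all(out_c2$kept))
})

test_that("wave filter removes ripple-induced calls, keeps sharp gains", {
  sim <- small_sim()
  cuts <- c(loss = 1.55, gain = 2.45)
  run_cell <- function(i, wave, plant) {
    tr <- truth_profile(sprintf("w%03d", i))
    if (plant) {
      tr <- plant_random_events(tr, sim, n = 1, size = 2.5e6, cn = 3,
                                seed = 1000 + i)
    }
    ns <- if (wave) noise_spec(amp_sd = 0.2, amp_corr = 0.95)
          else noise_spec(amp_sd = 0.1, amp_corr = 0)
    p <- simulate_cell(tr, ns, sim, seed = 2000 + i)
    v <- normalize_counts(p$counts, sim$grid, sim$genome)
    segs <- segment_profile(v, sim$grid, n_perm = 200, seed = 3000 + i)
    calls <- extract_calls(segs, 2, cuts, sim$genome, cell_id = tr$cell_id)
    cv <- stats::setNames(list(list(counts = p$counts, ploidy = 2)),
                          tr$cell_id)
    list(truth = tr$events,
         calls = filter_calls(calls, cv, sim$grid, sim$genome, cuts))
  }
  # wave-only cells: every extracted call is spurious
  wave_calls <- dplyr::bind_rows(lapply(1:8, function(i) {
    run_cell(i, TRUE, FALSE)$calls
  }))
  ge3 <- dplyr::filter(wave_calls, n_bins >= 3)
  expect_gt(nrow(ge3), 50L)
  expect_gte(mean(!ge3$kept), 0.8)

  # clean cells with one sharp planted gain: retained
  res <- lapply(26:45, function(i) run_cell(i, FALSE, TRUE))
  retained <- vapply(res, function(r) {
    k <- dplyr::filter(r$calls, .data$kept, .data$kind == "gain",
                       .data$chrom == r$truth$chrom[1],
                       abs(.data$start - r$truth$start[1]) < 1e6)
    nrow(k) > 0
  }, logical(1))
  expect_gte(mean(retained), 0.95)
})

test_that("chromosome-scale events are classified correctly", {
  g <- tiny_genome()
  calls <- tibble::tibble(
    cell_id = c("c1", "c2", "c2", "c3"),
    chrom = c("chr1", "chr2", "chr2", "chr1"),
    start = c(0, 0, 6e6, 2e6),
    end = c(1e7, 6e6, 8e6, 5e6),
    n_bins = c(40L, 24L, 8L, 12L),
    cn_real = c(1.02, 3.0, 2.04, 2.9),
    cn_int = c(1, 3, 2, 3),
    kind = c("loss", "gain", "gain", "gain"),
    aneusomy_candidate = c(TRUE, FALSE, FALSE, FALSE)
  )
  out <- classify_chromosome_events(calls, c(c1 = 2, c2 = 2, c3 = 4))
  expect_equal(out$event_class,
               c("pure_aneusomy", "sub_chromosomal", "sub_chromosomal",
                 "polyploidy"))
})

test_that("a constitutive duplication is called in every passing cell", {
  sim <- small_sim()
  ev <- tibble::tibble(chrom = "chr3", start = 2e7, end = 2e7 + 7 * 250e3,
                       cn = 3) # 7-bin germline-like gain
  profiles <- lapply(1:6, function(i) {
    tr <- plant_events(truth_profile(sprintf("g%02d", i)), ev, sim$genome)
    tr <- plant_random_events(tr, sim, n = 1, size = 3e6,
                              cn = ifelse(i %% 2, 1, 3), seed = 700 + i)
    simulate_cell(tr, noise_spec(amp_sd = 0.1), sim, seed = 800 + i)
  })
  batch <- call_cells(profiles, sim, seed = 900)
  passing <- batch$qc$cell_id[batch$qc$pass]
  expect_gte(length(passing), 5L)
  kept <- dplyr::filter(batch$calls, .data$kept, .data$kind == "gain",
                        .data$chrom == "chr3",
                        pmin(.data$end, 2e7 + 1.75e6) -
                          pmax(.data$start, 2e7) >= 1.25e6)
  expect_setequal(intersect(kept$cell_id, passing), passing)
})

test_that("QC gates reject exactly the cells beyond each threshold", {
  sim <- small_sim()
  mk <- function(id, ns, seed) {
    simulate_cell(truth_profile(id), ns, sim, seed = seed)
  }
  profiles <- list(
    mk("ok", noise_spec(depth = 1e6, amp_sd = 0.1), 31),
    mk("noisy", noise_spec(depth = 1e6, amp_sd = 0.45), 32),
    mk("shallow", noise_spec(depth = 5e5, amp_sd = 0.1), 33)
  )
  batch <- call_cells(profiles, sim, seed = 34)
  qc <- batch$qc
  expect_true(qc$pass[qc$cell_id == "ok"])
  noisy <- qc[qc$cell_id == "noisy", ]
  expect_false(noisy$pass)
  expect_match(noisy$fail_reasons, "mapd")
  shallow <- qc[qc$cell_id == "shallow", ]
  expect_false(shallow$pass)
  expect_match(shallow$fail_reasons, "reads")
  # no QC-failing cell yields calls
  expect_true(all(batch$calls$cell_id == "ok"))
})
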