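# Clonality, composition, size comparison, inclusion association, gene
# annotation, boundary windows and enrichment z-scores.

test_that("detect_clones groups matching calls and respects tolerance", {
  calls <- tibble::tibble(
    cell_id = c("c1", "c2"),
    chrom = "chr1", start = c(1e7, 1e7), end = c(1.4e7, 1.4e7),
    kind = "gain"
  )
  g <- detect_clones(calls)
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_members, 2L)

  apart <- dplyr::mutate(calls, start = c(1e7, 1.2e7), end = c(1.4e7, 1.6e7))
  expect_equal(nrow(detect_clones(apart, tolerance = 1e6)), 0L)

  # different copy number but matching boundaries can share a clone
  cn_mix <- dplyr::mutate(calls, cn_int = c(3, 4))
  expect_equal(nrow(detect_clones(cn_mix)), 1L)

  # same-cell duplicates alone do not make a clone group
  same_cell <- dplyr::mutate(calls, cell_id = c("c1", "c1"))
  expect_equal(nrow(detect_clones(same_cell)), 0L)

  # opposite kinds never group
  kinds <- dplyr::mutate(calls, kind = c("gain", "loss"))
  expect_equal(nrow(detect_clones(kinds)), 0L)
})

test_that("detect_clones is order-independent and finds planted clones", {
  genome <- small_sim()$genome
  set.seed(41)
  for (rep in 1:10) {
    clone <- tibble::tibble(
      cell_id = paste0("m", 1:3),
      chrom = "chr2",
      start = 1.5e7 + round(runif(3, -4e5, 4e5)),
      end = 2.1e7 + round(runif(3, -4e5, 4e5)),
      kind = "gain"
    )
    decoys <- make_decoy_calls(genome, 20, avoid = clone)
    calls <- dplyr::bind_rows(clone, decoys)
    shuffled <- calls[sample(nrow(calls)), ]
    g1 <- detect_clones(calls)
    g2 <- detect_clones(shuffled)
    expect_equal(nrow(g1), 1L)
    expect_equal(nrow(g2), 1L)
    expect_setequal(g1$cell_ids[[1]], paste0("m", 1:3))
    expect_setequal(g2$cell_ids[[1]], paste0("m", 1:3))
  }
})

test_that("clones are not detected when jitter exceeds the tolerance", {
  set.seed(43)
  for (rep in 1:10) {
    # offsets spaced >= 3.1 Mb apart: every pairwise boundary distance
    # exceeds the 1 Mb tolerance
    off <- sample(c(0, 3.5e6, 7e6)) + runif(3, -2e5, 2e5)
    calls <- tibble::tibble(
      cell_id = paste0("m", 1:3),
      chrom = "chr2",
      start = 1.5e7 + off,
      end = 2.1e7 + off,
      kind = "gain"
    )
    expect_equal(nrow(detect_clones(calls, tolerance = 1e6)), 0L)
  }
})

test_that("summarize_composition tallies gains/losses and excludes aneusomy", {
  meta <- tibble::tibble(cell_id = paste0("c", 1:6),
                         cell_type = rep(c("neuron", "non_neuron"), 3))
  calls <- tibble::tibble(
    cell_id = c("c1", "c1", "c2", "c3", "c5"),
    chrom = "chr1", start = 0, end = 1e6,
    kind = c("gain", "loss", "gain", "gain", "loss"),
    kept = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    event_class = c("sub_chromosomal", "sub_chromosomal", "sub_chromosomal",
                    "sub_chromosomal", "pure_aneusomy")
  )
  out <- summarize_composition(calls, meta)
  neuron <- out[out$cell_type == "neuron", ]
  expect_equal(neuron$n_gain, 1L) # c3 removed by filter, c5 aneusomy
  expect_equal(neuron$n_loss, 1L)
  expect_equal(neuron$n_cells, 3L)
  non <- out[out$cell_type == "non_neuron", ]
  expect_equal(non$n_cnv, 1L)
  expect_equal(non$gain_pct, 100)
  expect_error(summarize_composition(
    dplyr::mutate(calls, cell_id = "zz"), meta), "missing")
})

test_that("a 175/138 gain-loss split gives the reported fraction", {
  meta <- tibble::tibble(cell_id = "c1", cell_type = "neuron")
  calls <- tibble::tibble(
    cell_id = "c1", chrom = "chr1", start = 0, end = 1e6,
    kind = rep(c("gain", "loss"), c(175, 138)),
    kept = TRUE, event_class = "sub_chromosomal"
  )
  out <- summarize_composition(calls, meta)
  expect_equal(out$n_cnv, 313L)
  expect_equal(out$gain_pct, 55.9)
})

test_that("compare_sizes matches an exact enumeration and has power", {
  same <- compare_sizes(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$p_value, 1)

  set.seed(44)
  a <- rlnorm(10, log(6), 0.4)
  b <- rlnorm(10, log(3), 0.4)
  got <- compare_sizes(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(got$median_a, round(median(a), 2))

  # paper-scale n (186 gains in neurons vs 127 in non-neurons, medians
  # ~6.3 vs ~5.0 Mb): significant in most replicates
  hits <- 0L
  for (i in 1:100) {
    set.seed(500 + i)
    x <- rlnorm(186, log(6.3), 0.55)
    y <- rlnorm(127, log(5.0), 0.55)
    hits <- hits + (compare_sizes(x, y)$p_value < 0.05)
  }
  expect_gte(hits / 100, 0.8)
})

test_that("inclusion_association reproduces the printed stratum statistics", {
  tabs <- snca_inclusion_tables()
  cells <- tidyr::uncount(
    tidyr::pivot_longer(tabs, c("a", "b", "c", "d"),
                        names_to = "cell_class", values_to = "n"),
    .data$n
  ) |>
    dplyr::mutate(
      has_cnv = .data$cell_class %in% c("a", "b"),
      has_inclusion = .data$cell_class %in% c("a", "c")
    )
  res <- inclusion_association(
    dplyr::filter(cells, .data$stratum %in% c("msa_snd_nm_neg", "lb_nm_pos",
                                              "lb_nm_neg")),
    strata = "stratum"
  )
  msa <- res[res$stratum == "msa_snd_nm_neg", ]
  expect_equal(round(msa$rr, 2), 4.16)
  expect_equal(round(msa$or_, 1), 5.7)
  lb <- res[res$stratum == "lb_nm_pos", ]
  expect_equal(round(lb$rr, 2), 6.03)
  expect_equal(round(lb$p_fisher, 4), 0.0042)
  # zero inclusions among CNV+ cells: RR 0, Fisher p = 1
  lbn <- res[res$stratum == "lb_nm_neg", ]
  expect_equal(lbn$rr, 0)
  expect_equal(round(lbn$p_fisher, 2), 1)
})

test_that("annotate_genes matches a brute-force overlap scan", {
  sim <- small_sim()
  genes <- sim$genes
  set.seed(46)
  calls <- tibble::tibble(
    chrom = sample(paste0("chr", 1:4), 30, replace = TRUE),
    start = floor(runif(30, 0, 4e7))
  )
  calls$end <- calls$start + floor(runif(30, 1e6, 8e6))
  ann <- annotate_genes(calls, genes)
  for (i in seq_len(nrow(calls))) {
    hit <- genes$name[genes$chrom == calls$chrom[i] &
                        genes$start < calls$end[i] &
                        genes$end > calls$start[i]]
    expect_setequal(ann$genes[[i]], hit)
  }
  # a call containing the SNCA locus is flagged
  snca_call <- tibble::tibble(chrom = sim$snca_locus$chrom,
                              start = sim$snca_locus$start - 2e6,
                              end = sim$snca_locus$end + 2e6)
  expect_true(annotate_genes(snca_call, genes)$hits_locus_of_interest)
  none <- tibble::tibble(chrom = "chr1", start = 0, end = 1)
  expect_equal(annotate_genes(none, genes)$genes[[1]], character())
})

test_that("boundary windows are centred, clipped and flagged", {
  g <- tiny_genome()
  call <- tibble::tibble(chrom = "chr1", start = 5e6, end = 8e6)
  w <- boundary_windows(call, g)
  expect_equal(w$start, c(4.5e6, 7.5e6))
  expect_equal(w$end, c(5.5e6, 8.5e6))
  expect_false(any(w$clipped))

  near0 <- tibble::tibble(chrom = "chr1", start = 2e5, end = 3e6)
  w0 <- boundary_windows(near0, g)
  left <- w0[w0$side == "left", ]
  expect_equal(left$start, 0)
  expect_equal(left$end, 7e5)
  expect_true(left$clipped)

  set.seed(47)
  calls <- tibble::tibble(chrom = "chr1",
                          start = floor(runif(50, 2e6, 4e6)))
  calls$end <- calls$start + 2e6
  wr <- boundary_windows(calls, g)
  expect_true(all(wr$end - wr$start == 1e6 | wr$clipped))
})

test_that("enrichment_z flags planted hotspots and stays calibrated", {
  g <- genome_model(setNames(rep(1e8, 10), paste0("chr", 1:10)),
                    sex_chroms = character())
  withr::with_seed(48, {
    feats <- random_regions(g, 3000, 1e4, seed = 49)
    null <- random_regions(g, 3000, 1e6, seed = 50)
    # uniform feature: a window inside a 10x-density hotspot scores high
    hot <- tibble::tibble(chrom = "chr1",
                          start = seq(2e7, 2.1e7 - 1e3, by = 1e3))
    hot$end <- hot$start + 500
    ez <- enrichment_z(tibble::tibble(chrom = "chr1", start = 2.0e7,
                                      end = 2.1e7),
                       dplyr::bind_rows(feats, hot), null)
    expect_equal(ez$status, "enriched")
    expect_gt(ez$z, 1.96)

    # genome-covering feature: observed equals the null mean, z ~ 0
    full <- tibble::tibble(chrom = names(g$chrom_lengths), start = 0,
                           end = unname(g$chrom_lengths))
    ez0 <- suppressWarnings(
      enrichment_z(random_regions(g, 50, 1e6, seed = 51), full, null)
    )
    expect_true(all(ez0$degenerate_null) || all(abs(ez0$z) < 0.2))
  })
})

test_that("enrichment summary fractions agree with an independent tally", {
  sim <- small_sim()
  set.seed(52)
  calls <- tibble::tibble(
    cell_id = sample(c("n1", "n2", "x1"), 12, replace = TRUE),
    chrom = sample(paste0("chr", 1:4), 12, replace = TRUE),
    start = floor(runif(12, 2e6, 3e7))
  )
  calls$end <- calls$start + floor(runif(12, 2e6, 1e7))
  meta <- tibble::tibble(cell_id = c("n1", "n2", "x1"),
                         cell_type = c("neuron", "neuron", "non_neuron"))
  es <- enrichment_summary(calls, sim$tracks, meta, sim$genome,
                           n_null = 500, seed = 53)
  for (f in unique(es$fractions$feature)) {
    for (ct in unique(es$fractions$cell_type)) {
      sub <- es$boundaries[es$boundaries$feature == f, ]
      sub <- dplyr::left_join(sub, meta, by = "cell_id")
      sub <- sub[sub$cell_type == ct, ]
      row <- es$fractions[es$fractions$feature == f &
                            es$fractions$cell_type == ct, ]
      expect_equal(row$n_enriched, sum(sub$status == "enriched"))
      expect_equal(row$pct_enriched,
                   round(100 * mean(sub$status == "enriched"), 2))
    }
  }
})

test_that("SD-flanked calls are enriched at both boundaries", {
  sim <- small_sim()
  h <- sim$hotspots[1, ]
  planted <- tibble::tibble(cell_id = c("p1", "p2"), chrom = h$chrom,
                            start = h$start, end = h$end, kind = "gain")
  decoys <- make_decoy_calls(sim$genome, 8, avoid = planted)
  calls <- dplyr::bind_rows(planted, decoys)
  meta <- tibble::tibble(cell_id = calls$cell_id, cell_type = "neuron")
  es <- enrichment_summary(calls, sim$tracks["segdup"], meta, sim$genome,
                           n_null = 1000, seed = 54)
  both <- es$both_boundaries
  expect_true(all(1:2 %in% both$call_idx))
  pp <- both$paralog_pairs[both$call_idx == 1][[1]]
  expect_true(any(grepl("hotspot", pp)))
})
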