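# Normalisation, segmentation and ploidy fitting for single-cell profiles.

#' Normalise binned counts to relative coverage
#'
#' Converts per-bin read counts to relative values `v` with autosomal mean
#' exactly 1: counts are first divided by bin width (so the shortened last
#' bin of a chromosome is not depressed), then by the mean autosomal
#' per-base rate. Sex chromosomes are normalised on the same scale.
#'
#' @param counts Numeric vector of per-bin read counts (grid order).
#' @param grid A [bin_grid()].
#' @param genome The [genome_model()] the grid was built from.
#' @return Numeric vector of relative values, same length as `counts`.
#' @export
normalize_counts <- function(counts, grid, genome) {
  if (length(counts) != nrow(grid)) {
    abort("`counts` length must equal the number of grid bins")
  }
  if (any(counts < 0)) abort("counts must be non-negative")
  auto <- grid$chrom %in% autosomes(genome)
  rate <- counts / (grid$end - grid$start)
  m <- mean(rate[auto])
  if (m == 0) abort("profile has no autosomal reads")
  rate / m
}

#' Segment a per-bin profile by recursive binary splitting
#'
#' Within each chromosome, recursively finds the candidate sub-segment
#' maximising the two-sample t statistic between the segment and the rest of
#' the chromosome (the circular-binary-segmentation form, which has power
#' for short interior events that edge-anchored splits miss), accepting it
#' when a permutation test (default 1000 permutations) on that scan
#' statistic gives p < `alpha`. The scan is exhaustive over all
#' (start, length) pairs for stretches up to 60 bins and uses a multiscale
#' length grid with local boundary refinement above that. Recursion
#' continues into the three resulting parts until no scan is accepted or a
#' part is shorter than `2 * min_bins`. The Y chromosome is never segmented
#' (no copy-number calls are attempted there).
#'
#' @param values Numeric vector over the grid (normalised coverage).
#' @param grid A [bin_grid()].
#' @param alpha Acceptance level for the permutation test (default 0.01).
#' @param min_bins Minimum segment length in bins (default 2).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed for the permutation draws.
#' @return A tibble of segments: `chrom`, `start`, `end`, `first_bin`,
#'   `last_bin`, `n_bins`, `mean` (mean of `values` over the segment).
#' @export
segment_profile <- function(values, grid, alpha = 0.01, min_bins = 2,
                            n_perm = 1000, seed = NULL) {
  if (length(values) != nrow(grid)) {
    abort("`values` length must equal the number of grid bins")
  }
  if (min_bins < 2) abort("`min_bins` must be >= 2")
  with_seed_or_stream(seed, {
    chroms <- unique(grid$chrom)
    chroms <- chroms[chroms != "chrY"]
    segs <- purrr::map_dfr(chroms, function(chrom) {
      idx <- which(grid$chrom == chrom)
      bps <- find_breakpoints(values[idx], alpha, min_bins, n_perm)
      bounds <- c(0L, bps, length(idx))
      tibble(
        chrom = chrom,
        first_bin = idx[1] + head(bounds, -1),
        last_bin = idx[1] - 1L + tail(bounds, -1)
      )
    })
    segs |>
      mutate(
        start = grid$start[.data$first_bin],
        end = grid$end[.data$last_bin],
        n_bins = .data$last_bin - .data$first_bin + 1L,
        mean = purrr::map2_dbl(.data$first_bin, .data$last_bin,
                               ~ mean(values[.x:.y]))
      ) |>
      select("chrom", "start", "end", "first_bin", "last_bin", "n_bins",
             "mean")
  })
}

# Recursive segmentation of one chromosome; returns breakpoint positions
# (bins to the left of each break), relative to the vector.
find_breakpoints <- function(x, alpha, min_bins, n_perm) {
  n <- length(x)
  if (n < 2 * min_bins) {
    return(integer())
  }
  best <- scan_best(x, min_bins)
  if (is.null(best) ||
      !scan_significant(x, best$stat, min_bins, n_perm, alpha)) {
    return(integer())
  }
  i <- best$start      # segment is x[(i+1):j]
  j <- best$start + best$len
  bps <- c(if (i > 0L) i, if (j < n) j)
  parts <- list(c(1L, i), c(i + 1L, j), c(j + 1L, n))
  for (p in parts) {
    if (p[2] - p[1] + 1L >= 2 * min_bins) {
      sub <- find_breakpoints(x[p[1]:p[2]], alpha, min_bins, n_perm)
      bps <- c(bps, p[1] - 1L + sub)
    }
  }
  sort(unique(bps))
}

# Candidate segment lengths for the scan: exhaustive for short stretches,
# otherwise a ~25%-spaced multiscale grid (every start is still scanned).
candidate_lengths <- function(n, min_bins) {
  lmax <- n - min_bins
  if (lmax < min_bins) {
    return(integer())
  }
  if (n <= 60L) {
    return(seq.int(min_bins, lmax))
  }
  ls <- min_bins
  while (tail(ls, 1) < lmax) {
    ls <- c(ls, min(lmax, max(tail(ls, 1) + 1L,
                              ceiling(tail(ls, 1) * 1.25))))
  }
  ls
}

# |t| between x[(s+1):(s+L)] and the rest, for all starts s at one length L.
# cs0/css0 are 0-padded cumulative sums of x and x^2.
segment_t_stats <- function(cs0, css0, n, L) {
  s <- 0:(n - L)
  s_in <- cs0[s + L + 1] - cs0[s + 1]
  q_in <- css0[s + L + 1] - css0[s + 1]
  s_out <- cs0[n + 1] - s_in
  q_out <- css0[n + 1] - q_in
  n_out <- n - L
  m_in <- s_in / L
  m_out <- s_out / n_out
  ss <- pmax(0, (q_in - s_in^2 / L) + (q_out - s_out^2 / n_out))
  se <- sqrt(ss / max(n - 2, 1) * (1 / L + 1 / n_out))
  t <- abs(m_in - m_out) / se
  t[se == 0 & m_in == m_out] <- 0
  t[se == 0 & m_in != m_out] <- Inf
  t
}

# Maximum scan statistic of one vector over the candidate grid.
scan_max <- function(x, min_bins) {
  n <- length(x)
  cs0 <- c(0, cumsum(x))
  css0 <- c(0, cumsum(x^2))
  best <- list(stat = -Inf, start = NA_integer_, len = NA_integer_)
  for (L in candidate_lengths(n, min_bins)) {
    t <- segment_t_stats(cs0, css0, n, L)
    k <- which.max(t)
    if (t[k] > best$stat) {
      best <- list(stat = t[k], start = k - 1L, len = L)
    }
  }
  if (!is.finite(best$stat) && best$stat == -Inf) NULL else best
}

# Best segment with boundaries refined by local exhaustive search around the
# scanned optimum (the scan statistic itself stays unrefined so the
# permutation test compares like with like).
scan_best <- function(x, min_bins) {
  best <- scan_max(x, min_bins)
  if (is.null(best) || best$stat == 0) {
    return(NULL)
  }
  n <- length(x)
  if (n <= 60L) {
    return(best)
  }
  cs0 <- c(0, cumsum(x))
  css0 <- c(0, cumsum(x^2))
  pad <- max(3L, ceiling(0.15 * best$len) + 2L)
  refined <- best
  for (L in max(min_bins, best$len - pad):min(n - min_bins,
                                              best$len + pad)) {
    t <- segment_t_stats(cs0, css0, n, L)
    lo <- max(1L, best$start - pad + 1L)
    hi <- min(length(t), best$start + pad + 1L)
    k <- lo - 1L + which.max(t[lo:hi])
    if (t[k] > refined$stat ||
        (t[k] == refined$stat && L < refined$len)) {
      refined <- list(stat = t[k], start = k - 1L, len = L)
    }
  }
  refined$stat <- best$stat # test on the unrefined scan maximum
  refined
}

# Permutation test: p = (1 + #exceedances) / (n_perm + 1), rejected early as
# soon as the exceedance count makes p >= alpha whatever the remaining
# permutations would show (identical decision, much cheaper for flat data).
scan_significant <- function(x, stat_obs, min_bins, n_perm, alpha) {
  if (!is.finite(stat_obs) && stat_obs == Inf) {
    # a noiseless step: a permutation matches only by recreating a perfect
    # two-level arrangement, which the >= comparison still counts
    stat_obs <- .Machine$double.xmax
  }
  n <- length(x)
  reject_at <- ceiling(alpha * (n_perm + 1)) - 1
  lengths <- candidate_lengths(n, min_bins)
  exceed <- 0L
  done <- 0L
  while (done < n_perm) {
    # a small first chunk lets clearly non-significant scans exit cheaply
    b <- min(if (done == 0L) 40L else 150L, n_perm - done)
    xp <- vapply(seq_len(b), function(r) x[sample.int(n)], numeric(n))
    cs0 <- rbind(0, apply(xp, 2, cumsum))
    css0 <- rbind(0, apply(xp^2, 2, cumsum))
    tot_s <- cs0[n + 1, ]
    tot_q <- css0[n + 1, ]
    mx <- rep(-Inf, b)
    for (L in lengths) {
      rows_hi <- (L + 1):(n + 1)
      rows_lo <- 1:(n - L + 1)
      s_in <- cs0[rows_hi, , drop = FALSE] - cs0[rows_lo, , drop = FALSE]
      q_in <- css0[rows_hi, , drop = FALSE] - css0[rows_lo, , drop = FALSE]
      n_out <- n - L
      s_out <- rep(tot_s, each = nrow(s_in)) - s_in
      q_out <- rep(tot_q, each = nrow(q_in)) - q_in
      ss <- pmax((q_in - s_in^2 / L) + (q_out - s_out^2 / n_out), 0)
      se2 <- ss / max(n - 2, 1) * (1 / L + 1 / n_out)
      num <- (s_in / L - s_out / n_out)^2
      t2 <- ifelse(se2 == 0, ifelse(num == 0, 0, Inf), num / se2)
      mx <- pmax(mx, sqrt(apply(t2, 2, max)))
    }
    exceed <- exceed + sum(mx >= stat_obs)
    if (exceed > reject_at) {
      return(FALSE)
    }
    done <- done + b
  }
  (1 + exceed) / (n_perm + 1) < alpha
}

#' Fit the integer-ploidy scale of a segmented profile
#'
#' Grid search over candidate multipliers `c` in `[1.5, 6]` (step 0.05)
#' minimising the distance of the scaled per-bin segment means from integers,
#' \eqn{\sum_i (c\,m_i - \mathrm{round}(c\,m_i))^2} over autosomal bins,
#' where `m_i` is the mean of bin `i`'s segment. Ties go to the smaller
#' multiplier, so a featureless diploid profile scales to 2, not 4.
#'
#' @param segments Segment tibble from [segment_profile()].
#' @param grid A [bin_grid()].
#' @param genome The [genome_model()].
#' @param c_grid Candidate multipliers.
#' @return The fitted ploidy scale (a single number).
#' @export
fit_ploidy <- function(segments, grid, genome,
                       c_grid = seq(1.5, 6, by = 0.05)) {
  m <- per_bin_segment_means(segments, nrow(grid))
  auto <- grid$chrom %in% autosomes(genome)
  v <- m[auto & !is.na(m)]
  sse <- vapply(c_grid, function(cc) {
    y <- cc * v
    sum((y - round(y))^2)
  }, numeric(1))
  c_grid[which(sse <= min(sse) + 1e-9)[1]]
}

# Per-bin vector of segment means (NA for bins outside any segment, i.e. Y).
per_bin_segment_means <- function(segments, n_bins) {
  m <- rep(NA_real_, n_bins)
  for (i in seq_len(nrow(segments))) {
    m[segments$first_bin[i]:segments$last_bin[i]] <- segments$mean[i]
  }
  m
}
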