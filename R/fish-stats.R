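# Mosaicism quantification and 2x2 / nonparametric statistics.
#
# Conventions for 2x2 tables throughout: rows are exposure (e.g. CNV+ / CNV-),
# columns are outcome (e.g. inclusion+ / inclusion-):
#
#            outcome+  outcome-
#  exposed      a         b
#  unexposed    c         d

# Canonicalise the many ways a 2x2 table can arrive (4 scalars, a length-4
# vector a,b,c,d, or a 2x2 matrix in row-major exposure layout).
as_counts2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    x <- c(a = a[1, 1], b = a[1, 2], c = a[2, 1], d = a[2, 2])
  } else if (length(a) == 4L && is.null(b)) {
    x <- setNames(as.numeric(a), c("a", "b", "c", "d"))
  } else {
    x <- c(a = a, b = b, c = c, d = d)
  }
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    abort("2x2 counts must be non-negative integers")
  }
  if (sum(x) == 0) {
    abort("2x2 table must contain at least one count")
  }
  x
}

#' Mosaicism fraction with exact binomial confidence interval
#'
#' Computes, per row, the percentage of analysed cells carrying a unique gain
#' (the mosaicism level), with a Clopper-Pearson 95% confidence interval.
#' Percentages are reported to 2 decimal places, matching how such tables are
#' conventionally printed.
#'
#' @param data Data frame with one row per case/group.
#' @param gains,analysed Column names (unquoted) holding the gain and analysed
#'   cell counts. Defaults `n_gain` and `n_analysed`.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return `data` with columns `percent`, `ci_low`, `ci_high` appended (all on
#'   the percent scale).
#' @export
#' @examples
#' mosaicism_fraction(tibble::tibble(n_gain = 38, n_analysed = 1359))
mosaicism_fraction <- function(data, gains = n_gain, analysed = n_analysed,
                               conf_level = 0.95) {
  g <- dplyr::pull(data, {{ gains }})
  n <- dplyr::pull(data, {{ analysed }})
  if (any(n == 0)) {
    abort("`analysed` must be positive for every row")
  }
  if (any(g < 0 | g > n)) {
    abort("gain counts must satisfy 0 <= gains <= analysed")
  }
  ci <- purrr::map2(g, n, function(gi, ni) {
    stats::binom.test(gi, ni, conf.level = conf_level)$conf.int
  })
  dplyr::mutate(
    data,
    percent = round(100 * g / n, 2),
    ci_low = round(100 * purrr::map_dbl(ci, 1), 2),
    ci_high = round(100 * purrr::map_dbl(ci, 2), 2)
  )
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p-value by probability-mass ordering: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (within a relative tolerance of
#' 1e-7, the convention of mainstream statistical software). Degenerate
#' margins give p = 1.
#'
#' @param a,b,c,d Cell counts (exposed/outcome layout, see file header); `a`
#'   may instead be a length-4 vector or 2x2 matrix.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact(4, 7, 24, 374)
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- as_counts2x2(a, b, c, d)
  r1 <- x[["a"]] + x[["b"]]
  r2 <- x[["c"]] + x[["d"]]
  c1 <- x[["a"]] + x[["c"]]
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(x[["a"]], r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Chi-square test with Yates' continuity correction
#'
#' The classical corrected statistic
#' \eqn{\chi^2 = n\,(\max(|ad-bc| - n/2,\ 0))^2 / ((a+b)(c+d)(a+c)(b+d))}
#' referred to a chi-square distribution with 1 degree of freedom; used in
#' place of the exact test when counts are large. The correction is clamped
#' at zero, so a perfectly balanced table gives statistic 0 and p = 1.
#'
#' @inheritParams fisher_exact
#' @return Tibble with columns `statistic` and `p_value`.
#' @export
#' @examples
#' chi_square_yates(103, 3294, 19, 7592)
chi_square_yates <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- as_counts2x2(a, b, c, d)
  m <- matrix(x, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("chi-square requires all margins to be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  tibble(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Relative risk and odds ratio for a 2x2 table
#'
#' Point estimates with 95% confidence intervals: the relative risk interval
#' by the Katz log method, the odds ratio interval by the Woolf log method.
#' When a zero cell makes an estimate undefined the estimate is flagged and
#' its interval omitted; no continuity correction is applied. A two-sided
#' Fisher exact p-value is always attached, and the Yates chi-square p is
#' added for large samples (n > `yates_n`).
#'
#' @inheritParams fisher_exact
#' @param conf_level Confidence level (default 0.95).
#' @param yates_n Total count above which the Yates-corrected chi-square
#'   p-value is also reported (default 1000).
#'
#' @return An object of class `mosaic_assoc`; see [tidy.mosaic_assoc()] and
#'   [glance.mosaic_assoc()].
#' @export
#' @examples
#' risk_ratios(4, 7, 24, 374)
risk_ratios <- function(a, b = NULL, c = NULL, d = NULL,
                        conf_level = 0.95, yates_n = 1000) {
  x <- as_counts2x2(a, b, c, d)
  a <- x[["a"]]; b <- x[["b"]]; c <- x[["c"]]; d <- x[["d"]]
  n1 <- a + b
  n0 <- c + d
  if (n1 == 0 || n0 == 0) {
    abort("both exposure rows must contain at least one cell")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  flags <- character()

  rr <- (a / n1) / (c / n0)
  rr_ci <- c(NA_real_, NA_real_)
  if (a > 0 && c > 0) {
    se <- sqrt(1 / a - 1 / n1 + 1 / c - 1 / n0)
    rr_ci <- exp(log(rr) + c(-1, 1) * z * se)
  } else {
    flags <- c(flags, "rr_zero_cell")
  }

  or <- (a * d) / (b * c)
  or_ci <- c(NA_real_, NA_real_)
  if (all(c(a, b, c, d) > 0)) {
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    or_ci <- exp(log(or) + c(-1, 1) * z * se)
  } else {
    flags <- c(flags, "or_zero_cell")
  }

  n <- a + b + c + d
  p_yates <- if (n > yates_n && all(rowSums(matrix(x, 2, byrow = TRUE)) > 0) &&
                 all(colSums(matrix(x, 2, byrow = TRUE)) > 0)) {
    chi_square_yates(a, b, c, d)$p_value
  } else {
    NA_real_
  }

  structure(
    list(
      table = x,
      rr = rr, rr_ci_low = rr_ci[1], rr_ci_high = rr_ci[2],
      or = or, or_ci_low = or_ci[1], or_ci_high = or_ci[2],
      p_fisher = fisher_exact(a, b, c, d),
      p_chi2_yates = p_yates,
      conf_level = conf_level,
      flags = flags
    ),
    class = "mosaic_assoc"
  )
}

#' @export
print.mosaic_assoc <- function(x, ...) {
  cat(sprintf(
    "<mosaic_assoc> RR %.2f (%.2f-%.2f), OR %.2f (%.2f-%.2f), Fisher p = %.4g\n",
    x$rr, x$rr_ci_low, x$rr_ci_high, x$or, x$or_ci_low, x$or_ci_high,
    x$p_fisher
  ))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties. For small samples (n <= 10) the
#' two-sided p-value is computed by full enumeration of all n! rank
#' permutations (ties handled with midranks); for larger samples the
#' t-approximation is used.
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @return Tibble with `rho`, `p_value` and `method`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L) {
    abort("`x` and `y` must have equal length >= 4")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant input: Spearman correlation undefined")
    return(tibble(rho = NA_real_, p_value = NA_real_, method = "undefined"))
  }
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (n <= 10L) {
    p <- perm_rho_pvalue(rank(x), rank(y), rho)
    return(tibble(rho = rho, p_value = p, method = "exact permutation"))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  tibble(rho = rho, p_value = min(1, p), method = "t-approximation")
}

# Exact two-sided permutation p-value for the rank correlation, by full
# enumeration of the n! orderings (midrank ties kept fixed). Enumeration is
# chunked on the first element so n = 10 (3.6M permutations) stays within
# memory.
perm_rho_pvalue <- function(rx, ry, rho_obs) {
  n <- length(rx)
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  sub <- permutations_of(n - 1L)
  hits <- 0
  total <- 0
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    a <- matrix(ryc[block], nrow = nrow(block))
    rho_null <- as.numeric(a %*% rxc) / denom
    hits <- hits + sum(abs(rho_null) >= abs(rho_obs) - 1e-12)
    total <- total + nrow(block)
  }
  hits / total
}

# all permutations of 1..n as a matrix (n! rows); only used for small n
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Compare per-case percentages between two groups
#'
#' Two-sided Mann-Whitney U test with midranks, plus a Bonferroni adjustment
#' for the stated number of comparisons (capped at 1). The exact null
#' distribution is used for small untied samples.
#'
#' @param a,b Numeric vectors of per-case values for the two groups.
#' @param n_comparisons Number of comparisons the p-value is corrected for.
#' @return Tibble with `u`, `p_value`, `p_adjusted`.
#' @export
group_compare <- function(a, b, n_comparisons = 1) {
  if (length(a) == 0L || length(b) == 0L) {
    abort("both groups must be non-empty")
  }
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(tibble(u = length(a) * length(b) / 2, p_value = 1, p_adjusted = 1))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  tibble(
    u = unname(ht$statistic),
    p_value = ht$p.value,
    p_adjusted = min(1, ht$p.value * n_comparisons)
  )
}

#' Build stratified 2x2 tables of CNV status against inclusion status
#'
#' Tallies cells into exposure (CNV) by outcome (inclusion) tables per
#' stratum, and appends a pooled table over all cells. Layout per row:
#' `a` = CNV+ with inclusion, `b` = CNV+ without, `c` = CNV- with,
#' `d` = CNV- without.
#'
#' @param cells Data frame with logical columns `has_cnv`, `has_inclusion`
#'   and the stratifying columns.
#' @param strata Character vector of stratifying column names
#'   (default `c("disease", "cell_type")`).
#' @return Tibble with the strata columns and `a`, `b`, `c`, `d`; the pooled
#'   row carries `"Total"` in every stratum column.
#' @export
build_table2 <- function(cells, strata = c("disease", "cell_type")) {
  if (nrow(cells) == 0L) {
    abort("`cells` must contain at least one cell")
  }
  assert_columns(cells, c("has_cnv", "has_inclusion", strata), "cells")
  if (any(is.na(cells$has_cnv)) || any(is.na(cells$has_inclusion))) {
    abort("`has_cnv` and `has_inclusion` must be complete")
  }
  tally <- function(df) {
    tibble(
      a = sum(df$has_cnv & df$has_inclusion),
      b = sum(df$has_cnv & !df$has_inclusion),
      c = sum(!df$has_cnv & df$has_inclusion),
      d = sum(!df$has_cnv & !df$has_inclusion)
    )
  }
  per <- cells |>
    group_by(across(dplyr::all_of(strata))) |>
    dplyr::group_modify(~ tally(.x)) |>
    ungroup()
  pooled <- tally(cells)
  for (s in strata) pooled[[s]] <- "Total"
  bind_rows(per, pooled[, c(strata, "a", "b", "c", "d")])
}
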