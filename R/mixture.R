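# Three-component Gaussian mixture over segment copy numbers, and the
# copy-number cutoffs derived from its central (near-2) component.

#' Construct a copy-number mixture model
#'
#' Builds a `cnv_mixture` object directly from parameters (the fitted route
#' is [fit_cn_mixture()]). Components conventionally sit near copy numbers
#' 1, 2 and 3.
#'
#' @param weights,means,sds Numeric vectors of length 3; weights must sum
#'   to 1 and sds be positive.
#' @return An object of class `cnv_mixture`.
#' @export
#' @examples
#' cnv_mixture(c(.1, .8, .1), c(1, 2, 3), c(.1, 0.55 / qnorm(.995), .15))
cnv_mixture <- function(weights, means, sds) {
  stopifnot(length(weights) == 3L, length(means) == 3L, length(sds) == 3L)
  if (abs(sum(weights) - 1) > 1e-8) abort("weights must sum to 1")
  if (any(sds <= 0)) abort("sds must be positive")
  structure(
    list(weights = weights, means = means, sds = sds,
         loglik = NA_real_, loglik_trace = numeric(), n = NA_integer_,
         converged = NA, degenerate = FALSE, flags = character()),
    class = "cnv_mixture"
  )
}

#' Fit a three-Gaussian mixture to pooled segment copy numbers
#'
#' EM with three components initialised at means (1, 2, 3), free variances
#' and weights, run to a log-likelihood change below `tol` (or `max_iter`
#' iterations), with seeded random restarts keeping the best likelihood. The
#' input is the pooled copy numbers of all called segments across a batch of
#' cells, unweighted by segment length. A degenerate fit (any component
#' weight below 1e-4, a collapsed variance, or too few segments) falls back
#' to a robust location/scale estimate (median and MAD) of the values in
#' [1.6, 2.4], which still defines the central component the cutoffs need.
#'
#' @param cns Numeric vector of segment mean copy numbers (ploidy-scaled).
#' @param restarts Number of EM restarts (default 5; the first starts exactly
#'   at means 1, 2, 3, the rest jitter the initialisation).
#' @param max_iter,tol EM stopping rules.
#' @param min_segments Minimum number of segments to attempt EM (default 30).
#' @param seed Optional seed for the restart jitter.
#' @return A `cnv_mixture`; inspect with [tidy()] and [glance()].
#' @export
fit_cn_mixture <- function(cns, restarts = 5, max_iter = 500, tol = 1e-8,
                           min_segments = 30, seed = NULL) {
  cns <- cns[is.finite(cns)]
  if (length(cns) < min_segments) {
    return(mixture_fallback(cns, "too_few_segments"))
  }
  with_seed_or_stream(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      init_means <- if (r == 1L) c(1, 2, 3) else c(1, 2, 3) + rnorm(3, 0, 0.1)
      init_sds <- rep(max(0.05, sd(cns) / 3), 3)
      fit <- em_gaussian3(cns, init_means, init_sds, max_iter, tol)
      if (is.null(best) || (is.finite(fit$loglik) &&
                            fit$loglik > best$loglik)) {
        best <- fit
      }
    }
    if (any(best$weights < 1e-4) || any(best$sds < 1e-6)) {
      return(mixture_fallback(cns, "degenerate_component"))
    }
    structure(
      c(best, list(n = length(cns), degenerate = FALSE,
                   flags = character())),
      class = "cnv_mixture"
    )
  })
}

# Plain EM for a 3-component univariate Gaussian mixture.
em_gaussian3 <- function(x, means, sds, max_iter, tol) {
  n <- length(x)
  w <- rep(1 / 3, 3)
  loglik <- -Inf
  trace <- numeric()
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- vapply(1:3, function(k) w[k] * dnorm(x, means[k], sds[k]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    trace <- c(trace, ll)
    if (is.finite(loglik) && abs(ll - loglik) < tol) {
      converged <- TRUE
      loglik <- ll
      break
    }
    loglik <- ll
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.xmin
    w <- nk / n
    means <- colSums(resp * x) / nk
    sds <- sqrt(pmax(colSums(resp * (x - rep(means, each = n))^2) / nk,
                     1e-12))
  }
  list(weights = w, means = means, sds = sds, loglik = loglik,
       loglik_trace = trace, converged = converged)
}

mixture_fallback <- function(cns, flag) {
  central <- cns[cns >= 1.6 & cns <= 2.4]
  if (length(central) < 2L) {
    abort("cannot estimate the central component: too few segments near 2")
  }
  mu <- median(central)
  sigma <- max(mad(central), 1e-3)
  m <- cnv_mixture(c(1e-12, 1 - 2e-12, 1e-12), c(1, mu, 3),
                   c(sigma, sigma, sigma))
  m$degenerate <- TRUE
  m$flags <- flag
  m$n <- length(cns)
  m
}

#' @export
print.cnv_mixture <- function(x, ...) {
  cat("<cnv_mixture>\n")
  for (k in 1:3) {
    cat(sprintf("  component %d: weight %.3f, mean %.3f, sd %.3f\n",
                k, x$weights[k], x$means[k], x$sds[k]))
  }
  if (x$degenerate) cat("  degenerate fit:", x$flags, "\n")
  invisible(x)
}

#' Copy-number cutoffs from the central mixture component
#'
#' Inverts a cumulative two-tailed probability (default 1%) of the Gaussian
#' component nearest copy number 2: cutoffs are
#' \eqn{\mu_2 \pm z\,\sigma_2} with \eqn{z = \Phi^{-1}(1 - tail/2)}.
#' Segments below the loss cutoff or above the gain cutoff are treated as
#' real losses/gains; everything between is consistent with the diploid
#' state's amplification noise.
#'
#' @param m A `cnv_mixture`.
#' @param two_tailed Total two-tailed probability (default 0.01).
#' @return Named numeric vector `c(loss = , gain = )`, symmetric about the
#'   central mean.
#' @export
#' @examples
#' m <- cnv_mixture(c(.1, .8, .1), c(1, 2, 3), c(.1, 0.55 / qnorm(.995), .15))
#' mixture_cutoffs(m) # loss 1.45, gain 2.55
mixture_cutoffs <- function(m, two_tailed = 0.01) {
  stopifnot(inherits(m, "cnv_mixture"))
  if (two_tailed <= 0 || two_tailed >= 1) {
    abort("`two_tailed` must be in (0, 1)")
  }
  central <- which.min(abs(m$means - 2))
  mu <- m$means[central]
  sigma <- m$sds[central]
  if (sigma <= 0) abort("central component has non-positive sd")
  z <- qnorm(1 - two_tailed / 2)
  c(loss = mu - z * sigma, gain = mu + z * sigma)
}
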