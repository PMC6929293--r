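# broom-style tidiers for fitted objects.

#' Tidy a fitted copy-number mixture
#'
#' @param x A `cnv_mixture`.
#' @param ... Unused.
#' @return Tibble with one row per component: `component`, `weight`,
#'   `mean`, `sd`, `central` (is this the near-2 component the cutoffs are
#'   derived from).
#' @export
tidy.cnv_mixture <- function(x, ...) {
  tibble(
    component = 1:3,
    weight = x$weights,
    mean = x$means,
    sd = x$sds,
    central = seq_len(3) == which.min(abs(x$means - 2))
  )
}

#' Glance at a fitted copy-number mixture
#'
#' @param x A `cnv_mixture`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `loglik`, `n_iter`, `converged`,
#'   `degenerate`, `loss_cutoff`, `gain_cutoff` (at the default 1% tail).
#' @export
glance.cnv_mixture <- function(x, ...) {
  cuts <- mixture_cutoffs(x)
  tibble(
    n = x$n,
    loglik = x$loglik,
    n_iter = length(x$loglik_trace),
    converged = x$converged,
    degenerate = x$degenerate,
    loss_cutoff = unname(cuts[["loss"]]),
    gain_cutoff = unname(cuts[["gain"]])
  )
}

#' Tidy a 2x2 association result
#'
#' @param x A `mosaic_assoc` from [risk_ratios()].
#' @param ... Unused.
#' @return Tibble with rows `relative_risk` and `odds_ratio`: `term`,
#'   `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.mosaic_assoc <- function(x, ...) {
  tibble(
    term = c("relative_risk", "odds_ratio"),
    estimate = c(x$rr, x$or),
    conf.low = c(x$rr_ci_low, x$or_ci_low),
    conf.high = c(x$rr_ci_high, x$or_ci_high)
  )
}

#' Glance at a 2x2 association result
#'
#' @param x A `mosaic_assoc`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `p_fisher`, `p_chi2_yates`, `conf_level`,
#'   `flags`.
#' @export
glance.mosaic_assoc <- function(x, ...) {
  tibble(
    n = sum(x$table),
    p_fisher = x$p_fisher,
    p_chi2_yates = x$p_chi2_yates,
    conf_level = x$conf_level,
    flags = paste(x$flags, collapse = ",")
  )
}
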