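# ggplot2 views of the main result types.

#' Plot a cell's copy-number profile
#'
#' Per-bin ploidy-scaled copy number along the genome with segment means
#' overlaid; the classic single-cell CNV profile view.
#'
#' @param batch A `cnv_batch` from [call_cells()].
#' @param cell_id Which cell to plot.
#' @param sim The `sim_genome` the batch was called on.
#' @param values Optional normalised per-bin values for the cell (recomputed
#'   from the profile when the batch came from [call_cells()] on simulated
#'   profiles is not possible, so pass them when available).
#' @return A ggplot object.
#' @export
plot_cn_profile <- function(batch, cell_id, sim, values = NULL) {
  segs <- filter(batch$segments, .data$cell_id == !!cell_id)
  if (nrow(segs) == 0L) {
    abort(sprintf("no segments for cell '%s'", cell_id))
  }
  grid <- sim$grid
  ploidy <- batch$ploidy[[cell_id]]
  df_seg <- segs |>
    mutate(mid_start = .data$first_bin - 0.5, mid_end = .data$last_bin + 0.5)
  p <- ggplot()
  if (!is.null(values)) {
    df_bins <- tibble(bin = grid$bin, chrom = grid$chrom,
                      cn = ploidy * values)
    p <- p + geom_point(data = filter(df_bins, .data$chrom != "chrY"),
                        aes(x = .data$bin, y = .data$cn,
                            colour = .data$chrom),
                        size = 0.3, alpha = 0.5, show.legend = FALSE)
  }
  p +
    geom_segment(data = df_seg,
                 aes(x = .data$mid_start, xend = .data$mid_end,
                     y = .data$cn_real, yend = .data$cn_real),
                 linewidth = 1, colour = "firebrick") +
    scale_y_continuous(limits = c(0, NA)) +
    labs(x = "bin", y = "copy number",
         title = sprintf("%s (ploidy %.2f)", cell_id, ploidy)) +
    theme_minimal()
}

#' @rdname autoplot.cnv_mixture
#' @export
autoplot.cnv_batch <- function(object, ...) {
  if (is.null(object$mixture)) {
    abort("batch has no fitted mixture (no QC-passing cells)")
  }
  autoplot(object$mixture, cns = object$segments$cn_real, ...)
}

#' Plot a copy-number mixture with its cutoffs
#'
#' Histogram of segment copy numbers with the three fitted Gaussian
#' components and the loss/gain cutoffs derived from the central component.
#'
#' @param object A `cnv_mixture` (or `cnv_batch`).
#' @param cns Optional vector of segment copy numbers to show as a
#'   histogram.
#' @param two_tailed Tail probability for the cutoff lines (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnv_mixture <- function(object, cns = NULL, two_tailed = 0.01,
                                 ...) {
  cuts <- mixture_cutoffs(object, two_tailed)
  xs <- seq(0, 5, length.out = 400)
  dens <- purrr::map_dfr(1:3, function(k) {
    tibble(component = factor(k), x = xs,
           d = object$weights[k] * dnorm(xs, object$means[k],
                                         object$sds[k]))
  })
  p <- ggplot()
  if (!is.null(cns)) {
    p <- p + geom_histogram(data = tibble(cn = cns),
                            aes(x = .data$cn, y = after_stat(density)),
                            bins = 60, fill = "grey85", colour = "grey60")
  }
  p +
    geom_line(data = dens,
              aes(x = .data$x, y = .data$d, colour = .data$component)) +
    geom_vline(xintercept = unname(cuts), linetype = "dashed") +
    labs(x = "segment copy number", y = "density",
         subtitle = sprintf("cutoffs: loss < %.2f, gain > %.2f",
                            cuts[["loss"]], cuts[["gain"]])) +
    theme_minimal()
}

#' Plot mosaicism fractions by group
#'
#' Point-range view of per-group mosaicism percentages with their exact
#' binomial confidence intervals, as produced by [mosaicism_fraction()].
#'
#' @param data Output of [mosaicism_fraction()].
#' @param group Column (unquoted) to place on the x axis; defaults to
#'   `disease`.
#' @param facet Optional faceting column name (string), e.g. `"cell_type"`.
#' @return A ggplot object.
#' @export
plot_mosaicism <- function(data, group = disease, facet = NULL) {
  p <- ggplot(data, aes(x = {{ group }}, y = .data$percent)) +
    geom_pointrange(aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    labs(y = "mosaicism (%)") +
    theme_minimal()
  if (!is.null(facet)) {
    p <- p + facet_wrap(facet)
  }
  p
}
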