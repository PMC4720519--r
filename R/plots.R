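#' Plot dF/F0 traces with detected peaks
#'
#' One panel per cell: the normalised trace, the detection threshold, and
#' the apex of each detected oscillation.
#'
#' @param dff_traces Tibble from [compute_dff()].
#' @param peaks Optional peak tibble from [detect_peaks()].
#' @param threshold Optional `ca_threshold` (drawn as a dashed line).
#' @param cells Optional subset of cell ids to show.
#' @return A ggplot object.
#' @export
plot_traces <- function(dff_traces, peaks = NULL, threshold = NULL,
                        cells = NULL) {
  d <- dff_traces
  if (!is.null(cells)) d <- d[d$cell_id %in% cells, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s, y = .data$dff)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_id)) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F[0])) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    thr <- if (inherits(threshold, "ca_threshold")) threshold$threshold
           else threshold
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                 colour = "grey40")
  }
  if (!is.null(peaks)) {
    pk <- peaks
    if (!is.null(cells)) pk <- pk[pk$cell_id %in% cells, ]
    p <- p + ggplot2::geom_point(
      data = pk,
      ggplot2::aes(x = .data$apex_time_s, y = .data$apex_dff),
      colour = "red", size = 1
    )
  }
  p
}

#' Dot plot of a per-cell metric by group
#'
#' Mirrors the conventional per-cell dot plots (each dot one cell, bar at
#' the group mean) used for oscillation frequency and mean dF/F0.
#'
#' @param metrics Metric tibble with a `role` (or `group`) column.
#' @param value Metric column name (default `"frequency_per_min"`).
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics, value = "frequency_per_min") {
  grp <- if ("role" %in% names(metrics)) "role" else "group"
  d <- metrics[!is.na(metrics[[grp]]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[grp]], y = .data[[value]])) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 1.2, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "red") +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}

#' Dot-plot summary of a pipeline run
#' @param object A `ca_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ca_run
#' @export
autoplot.ca_run <- function(object, ...) {
  plot_metrics(object$metrics)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
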