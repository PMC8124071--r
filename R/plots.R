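#' Plot an activity map with detected ROIs
#'
#' @param map An `activity_map`.
#' @param rois Optional `roi_set` to overlay.
#' @return A ggplot object.
#' @export
plot_activity_map <- function(map, rois = NULL) {
  vals <- if (inherits(map, "activity_map")) map$values else map
  df <- tidyr::expand_grid(col = seq_len(ncol(vals)), row = seq_len(nrow(vals)))
  df$value <- as.vector(vals)   # row varies fastest: matches column-major layout
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "activity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  title = "Cumulative-difference activity map") +
    ggplot2::theme_minimal()
  if (!is.null(rois) && nrow(rois) > 0) {
    p <- p + ggplot2::geom_point(
      data = as_tibble(rois), inherit.aes = FALSE,
      ggplot2::aes(x = .data$col, y = .data$row),
      shape = 21, colour = "red", fill = NA, size = 3, stroke = 0.7)
  }
  p
}

#' Plot normalized traces with fitted event onsets
#'
#' @param traces Normalized traces ([normalize_dff()]).
#' @param events Optional fitted events ([fit_events()]); onsets are marked.
#' @param cell_ids Cells to show (default: the first 6).
#' @return A ggplot object (one facet per cell).
#' @export
plot_traces <- function(traces, events = NULL, cell_ids = NULL) {
  stopifnot("dff" %in% names(traces))
  ids <- cell_ids %||% head(unique(traces$cell_id), 6)
  d <- traces[traces$cell_id %in% ids, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$dff)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~cell_id, ncol = 1, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F[0])) +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    ev <- events[events$cell_id %in% ids & events$converged, ]
    if (nrow(ev) > 0) {
      p <- p + ggplot2::geom_vline(data = ev,
                                   ggplot2::aes(xintercept = .data$t0_s),
                                   colour = "red", linetype = 2,
                                   linewidth = 0.3)
    }
  }
  p
}

#' Cumulative-distribution comparison of a metric between two groups
#'
#' Empirical cumulative distributions of one per-FOV (or per-cell) metric
#' for two groups, the display behind Kolmogorov-Smirnov comparisons of
#' e.g. per-class event frequencies.
#'
#' @param group_a,group_b Data frames holding the metric.
#' @param metric Column name to compare.
#' @param labels Group labels.
#' @return A ggplot object.
#' @export
plot_cumulative <- function(group_a, group_b, metric, labels = c("A", "B")) {
  df <- dplyr::bind_rows(
    tibble(group = labels[1], value = group_a[[metric]]),
    tibble(group = labels[2], value = group_b[[metric]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$group)) +
    ggplot2::stat_ecdf(linewidth = 0.6) +
    ggplot2::labs(x = metric, y = "cumulative fraction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fov_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(object$by_class,
                            cols = c("mean_amplitude", "mean_event_rate_hz",
                                     "synchrony"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$class)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("FOV summary: %d/%d active cells",
                                  object$counts["n_active"],
                                  object$counts["n_total"])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.evoked_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$peak_response,
                               fill = .data$responder)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = expression((F - F[0]) / F[0]~peak), y = "cells") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
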