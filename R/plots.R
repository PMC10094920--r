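#' Firing-rate activity map
#'
#' Tile map of per-electrode mean firing rate on the grid, with the
#' intensity scale clipped at `ceiling_hz` (default 10 spikes/s, the display
#' ceiling used for developing-culture activity maps).
#'
#' @param mfr Output of [mean_firing_rate()].
#' @param ceiling_hz Display ceiling in spikes/s.
#' @return A ggplot object.
#' @export
plot_activity_map <- function(mfr, ceiling_hz = 10) {
  ggplot2::ggplot(mfr, ggplot2::aes(.data$x_mm, .data$y_mm,
                                    fill = pmin(.data$mfr_hz, ceiling_hz))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, ceiling_hz), name = "MFR (spikes/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' @describeIn spike_raster Raster plot of spike times by electrode, with
#'   optional network-burst shading.
#' @param object A `spike_raster`.
#' @param network_bursts Optional [detect_network_bursts()] table to shade.
#' @param ... Unused.
#' @export
autoplot.spike_raster <- function(object, network_bursts = NULL, ...) {
  ev <- object$spikes
  p <- ggplot2::ggplot(ev, ggplot2::aes(.data$time_s, .data$electrode_id))
  if (!is.null(network_bursts) && nrow(network_bursts) > 0) {
    p <- p + ggplot2::geom_rect(
      data = network_bursts, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s),
      ymin = -Inf, ymax = Inf, fill = "goldenrod", alpha = 0.4
    )
  }
  p + ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "electrode") +
    ggplot2::theme_minimal()
}

#' @describeIn compute_cat Trajectory plot coloured from initiation (gray)
#'   to termination (yellow), with the arena centre marked.
#' @param object A `cat_trajectory`.
#' @param ... Unused.
#' @export
autoplot.cat_trajectory <- function(object, ...) {
  pts <- object$points[object$points$defined, ]
  ggplot2::ggplot(pts, ggplot2::aes(.data$x_mm, .data$y_mm, colour = .data$t_s)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::annotate("point", x = 0, y = 0, shape = 3, size = 3) +
    ggplot2::scale_colour_gradient(low = "gray60", high = "gold", name = "t (s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' @describeIn infer_graph Connectivity map: nodes at electrode positions
#'   coloured by role (sender red, receiver blue, broker gray), edges as
#'   segments.
#' @param object A `functional_graph`.
#' @param ... Unused.
#' @export
autoplot.functional_graph <- function(object, ...) {
  nodes <- object$nodes
  edges <- object$edges
  if (nrow(edges) > 0) {
    edges <- edges |>
      dplyr::left_join(nodes[c("electrode_id", "x_mm", "y_mm")],
                       by = c(from = "electrode_id")) |>
      dplyr::rename(x0 = "x_mm", y0 = "y_mm") |>
      dplyr::left_join(nodes[c("electrode_id", "x_mm", "y_mm")],
                       by = c(to = "electrode_id")) |>
      dplyr::rename(x1 = "x_mm", y1 = "y_mm")
  }
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      colour = "gray80", linewidth = 0.3, alpha = 0.7
    )
  }
  p +
    ggplot2::geom_point(
      data = nodes[!is.na(nodes$role), ],
      ggplot2::aes(.data$x_mm, .data$y_mm, colour = .data$role), size = 2
    ) +
    ggplot2::scale_colour_manual(values = c(sender = "red3", receiver = "dodgerblue3",
                                            broker = "gray40")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
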