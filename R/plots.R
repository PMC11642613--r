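#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a slide as a labeled point map
#'
#' @param cells Cell tibble for one slide.
#' @param width,height Slide dimensions (micrometers).
#' @return A ggplot.
#' @export
plot_slide <- function(cells, width = 1000, height = 1000) {
  ggplot2::ggplot(cells, ggplot2::aes(.data$x, .data$y, colour = .data$cell_type)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::coord_fixed(xlim = c(0, width), ylim = c(0, height), expand = FALSE) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ensemble trajectories of one population
#'
#' @param traj Trajectory tibble.
#' @param variable Count column to plot.
#' @param log_y Use a log10 y axis (counts of 0 are dropped by the scale).
#' @return A ggplot.
#' @export
plot_trajectories <- function(traj, variable = "n_melanoma", log_y = TRUE) {
  p <- ggplot2::ggplot(
    traj,
    ggplot2::aes(.data$time_h, .data[[variable]], group = .data$sample_id)
  ) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3) +
    ggplot2::labs(x = "time (h)", y = variable) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.ics_trajectory <- function(object, variable = "n_melanoma", ...) {
  plot_trajectories(object, variable = variable, ...)
}

#' Score surface of a calibration fit
#'
#' Tile plot of the negative log prediction success score over the
#' `(bC, bM)` grid, with the estimate marked.
#'
#' @param object An `ics_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ics_fit <- function(object, ...) {
  ggplot2::ggplot(object$surface, ggplot2::aes(.data$bC, .data$bM)) +
    ggplot2::geom_tile(ggplot2::aes(fill = -.data$log_score)) +
    ggplot2::geom_point(
      data = object$estimate, colour = "white", shape = 4, size = 3, stroke = 1.2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(
      x = "bC (1/h)", y = "bM (1/h)", fill = "-log score"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of bootstrap DSS replicates
#'
#' @param object An `ics_dss`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ics_dss <- function(object, bins = 60, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$dss)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "DSS = log(score_alt) - log(score_base)", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Observed fencing fraction against its permutation null
#'
#' @param object An `ics_fencing_null`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ics_fencing_null <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$fraction)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(
      xintercept = object$observed, colour = "red", linewidth = 1
    ) +
    ggplot2::labs(x = "fencing fraction", y = "permutations") +
    ggplot2::theme_minimal()
}

#' Plot pair-correlation curves
#'
#' @param curve Tibble from [pair_correlation()].
#' @return A ggplot.
#' @export
plot_pair_correlation <- function(curve) {
  ggplot2::ggplot(
    curve,
    ggplot2::aes(.data$r, .data$value, group = .data$slide_id)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "r (µm)", y = "C(r)") +
    ggplot2::theme_minimal()
}
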