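#' @method autoplot wavefront_set
#' @export
autoplot.wavefront_set <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   color = .data$time_min)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_color_gradient(low = "grey85", high = "black",
                                  name = "time (min)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Hypoxic wavefront contours",
                  x = "column (px)", y = "row (px)") +
    ggplot2::annotate("point", x = object$origin[2], y = object$origin[1],
                      shape = 3, size = 2)
}

#' @method autoplot propagation_profile
#' @export
autoplot.propagation_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("distance_um", "speed_um_per_min"),
                            names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(title = sprintf("Expansion profile (%s)",
                                  attr(object, "direction_label") %||% "ray"),
                  x = "time (min)", y = NULL)
}

#' @method autoplot cluster_labeling
#' @export
autoplot.cluster_labeling <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_col, y = .data$cell_row,
                                   fill = factor(.data$niche))) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_d(name = "niche", na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Vasomotion niches", x = "sub-region column",
                  y = "sub-region row")
}

#' @method autoplot coupling_result
#' @export
autoplot.coupling_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_col, y = .data$cell_row,
                                   fill = .data$category)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(TIGHT = "#1b7837", POOR = "#762a83",
                                          INTERMITTENT = "#fdb863",
                                          MISSING = "grey90")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "BF-BV coupling categories", x = "sub-region column",
                  y = "sub-region row")
}

#' @method autoplot perturbation_response
#' @export
autoplot.perturbation_response <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_col, y = .data$cell_row,
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(name = "delta", na.value = "grey90") +
    ggplot2::facet_wrap(~variable) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Perturbation response magnitude",
                  x = "sub-region column", y = "sub-region row")
}

#' @method autoplot band_spectrum_map
#' @export
autoplot.band_spectrum_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_col, y = .data$cell_row,
                                   fill = .data$power_db)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "power (dB)", na.value = "grey90") +
    ggplot2::facet_wrap(~band) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Band power (%s)", object$variable),
                  x = "sub-region column", y = "sub-region row")
}

#' Acute-vs-normoxic reduction scatter
#'
#' Scatter of the blood-flow reduction against the blood-volume reduction per
#' sub-region, split by hypoxia zone.
#'
#' @param zones A [zone_scatter()] tibble.
#' @return A ggplot.
#' @export
plot_zone_scatter <- function(zones) {
  df <- dplyr::filter(zones, .data$zone != "CHRONIC")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neg_delta_bv,
                                   y = .data$neg_delta_bf,
                                   color = .data$zone)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(ACUTE = "grey25", NORMOXIC = "grey65")) +
    ggplot2::labs(title = "Hemodynamic reductions by zone",
                  x = "-dBV", y = "-dBF")
}
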