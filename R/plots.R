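#' Plot daily series over a haze episode
#'
#' Facets the daily values of each variable over the episode and shades
#' the haze-event days, the standard day-to-day overview figure for an
#' episode.
#'
#' @param daily Daily tibble (columns `variable`, `date`, `value`), e.g.
#'   rows bound from several [aggregate_daily()] calls.
#' @param event Optional windowed event row from [attach_windows()] used
#'   for shading.
#' @return A ggplot object.
#' @export
plot_episode_daily <- function(daily, event = NULL) {
  p <- ggplot2::ggplot(daily, ggplot2::aes(x = .data$date,
                                           y = .data$value))
  if (!is.null(event)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = event$start_date - 0.5, xmax = event$end_date + 0.5,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey20")
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sounding temperature profile with detected inversion layers
#'
#' @param profile Sounding tibble (`height_m`, `temp_c`).
#' @param layers Optional classified layers from [classify_inversions()];
#'   low-band layers are shaded blue, upper-band grey.
#' @param top Height ceiling shown, m.
#' @return A ggplot object.
#' @export
plot_sounding <- function(profile, layers = NULL, top = 4000) {
  p <- ggplot2::ggplot(
    dplyr::filter(profile, .data$height_m <= top),
    ggplot2::aes(x = .data$temp_c, y = .data$height_m))
  if (!is.null(layers) && nrow(layers)) {
    p <- p + ggplot2::geom_rect(
      data = layers,
      ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$z_bottom,
                   ymax = .data$z_top, fill = .data$band),
      alpha = 0.25, inherit.aes = FALSE) +
      ggplot2::scale_fill_manual(
        values = c(low = "steelblue", upper = "grey40"))
  }
  p +
    ggplot2::geom_path() +
    ggplot2::labs(x = "Temperature (°C)", y = "Height AGL (m)",
                  fill = "Inversion band") +
    ggplot2::theme_minimal()
}

#' Plot an hourly stability series
#'
#' Shows `zeta = z_u/L` against time, coloured by solver status, with the
#' neutral line at zero. Hours without a usable estimate are omitted.
#'
#' @param results [solve_obukhov()] output with a `timestamp` column.
#' @return A ggplot object.
#' @export
plot_stability <- function(results) {
  df <- dplyr::filter(results, is.finite(.data$zeta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp, y = .data$zeta,
                                   colour = .data$status)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = NULL, y = expression(zeta == z[u] / L),
                  colour = "status") +
    ggplot2::theme_minimal()
}

#' Plot gridded fire-hotspot counts per episode phase
#'
#' @param grid Output of [grid_hotspots()].
#' @return A ggplot object (tile map faceted by phase).
#' @export
plot_fire_grid <- function(grid) {
  cell <- attr(grid, "cell") %||% 0.5
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$lon_left + cell / 2,
                                     y = .data$lat_bottom + cell / 2,
                                     fill = .data$count)) +
    ggplot2::geom_tile(width = cell, height = cell) +
    ggplot2::facet_wrap(ggplot2::vars(.data$phase)) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  fill = "Hotspots") +
    ggplot2::theme_minimal()
}
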