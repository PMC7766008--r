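#' Grid active-fire hotspots by episode period
#'
#' Sums fire-detection points onto a regular latitude/longitude grid,
#' separately for the pre-event, event and post-event periods of a haze
#' episode. Cell edges are anchored at integer multiples of the cell size
#' and membership is half-open, `[edge, edge + cell)`, so a point exactly
#' on a lower edge belongs to that cell. Points outside the domain or
#' outside every period are dropped (with a message reporting how many).
#'
#' @param points Hotspot tibble with `latitude`, `longitude`, `acq_date`
#'   (see [read_hotspots_csv()]).
#' @param event One windowed event row from [attach_windows()].
#' @param domain Bounding box `c(lon_min, lon_max, lat_min, lat_max)`,
#'   degrees.
#' @param cell Cell size, degrees.
#' @param quiet Suppress the dropped-point message.
#' @return Tibble of non-empty cells: `phase`, `lon_left`, `lat_bottom`
#'   (lower cell edges, degrees), `count`. The sum of `count` within a
#'   phase equals the number of in-domain points dated in that phase.
#' @export
grid_hotspots <- function(points, event, domain, cell = 0.5,
                          quiet = FALSE) {
  stopifnot(length(domain) == 4, cell > 0,
            all(c("latitude", "longitude", "acq_date") %in% names(points)))
  if (domain[1] >= domain[2] || domain[3] >= domain[4]) {
    stop("degenerate domain: need lon_min < lon_max and lat_min < lat_max")
  }
  phase <- episode_phase(points$acq_date, event)
  in_dom <- points$longitude >= domain[1] & points$longitude < domain[2] &
    points$latitude >= domain[3] & points$latitude < domain[4]
  keep <- !is.na(phase) & in_dom
  if (!quiet) {
    rlang::inform(sprintf(
      "grid_hotspots: %d points kept, %d outside domain, %d outside periods",
      sum(keep), sum(!in_dom), sum(is.na(phase) & in_dom)))
  }
  pts <- points[keep, , drop = FALSE]
  out <- tibble::tibble(
    phase = factor(phase[keep], levels = c("pre", "haze", "post")),
    lon_left = floor(pts$longitude / cell) * cell,
    lat_bottom = floor(pts$latitude / cell) * cell
  ) |>
    dplyr::count(.data$phase, .data$lon_left, .data$lat_bottom,
                 name = "count") |>
    dplyr::mutate(phase = as.character(.data$phase)) |>
    dplyr::arrange(.data$phase, .data$lon_left, .data$lat_bottom)
  attr(out, "cell") <- cell
  attr(out, "domain") <- domain
  out
}
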