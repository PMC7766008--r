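#' Detect temperature-inversion layers in a sounding profile
#'
#' An inversion layer is a maximal run of successive sounding levels whose
#' temperature increases monotonically (strictly) with height. All levels
#' up to `top` metres are considered; an isothermal step terminates a run.
#' Each run of two or more levels yields one layer spanning the run's
#' endpoints, with intensity `IV = (T_top - T_bottom) / depth * 100` in
#' degC per 100 m.
#'
#' @param profile Sounding tibble with columns `height_m` (strictly
#'   increasing) and `temp_c`; other columns (pressure, dewpoint) are
#'   ignored. Heights are above ground level.
#' @param top Ceiling of the analysis, m; levels above it are dropped.
#' @return Tibble of unfiltered layers ordered by height: `z_bottom`,
#'   `z_top`, `t_bottom`, `t_top`, `depth_m`, `n_levels`, `iv`. Zero rows
#'   when no warming segment exists or fewer than two usable levels.
#' @export
#' @examples
#' prof <- tibble::tibble(height_m = c(200, 500, 800),
#'                        temp_c = c(20, 21.5, 21))
#' detect_inversions(prof)
detect_inversions <- function(profile, top = 4000) {
  stopifnot(all(c("height_m", "temp_c") %in% names(profile)))
  lv <- profile |>
    dplyr::filter(!is.na(.data$height_m), !is.na(.data$temp_c),
                  .data$height_m <= top) |>
    dplyr::arrange(.data$height_m)
  empty <- tibble::tibble(
    z_bottom = numeric(), z_top = numeric(), t_bottom = numeric(),
    t_top = numeric(), depth_m = numeric(), n_levels = integer(),
    iv = numeric())
  n <- nrow(lv)
  if (n < 2) return(empty)
  if (any(diff(lv$height_m) <= 0)) {
    stop("sounding heights must be strictly increasing")
  }
  warming <- diff(lv$temp_c) > 0          # level i -> i+1 warms
  runs <- rle(warming)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  if (!any(keep)) return(empty)
  purrr::map2_dfr(starts[keep], ends[keep], function(s, e) {
    # run of warming steps s..e spans levels s .. e+1
    tibble::tibble(
      z_bottom = lv$height_m[s], z_top = lv$height_m[e + 1],
      t_bottom = lv$temp_c[s], t_top = lv$temp_c[e + 1],
      depth_m = lv$height_m[e + 1] - lv$height_m[s],
      n_levels = e + 1L - s + 1L,
      iv = (lv$temp_c[e + 1] - lv$temp_c[s]) /
        (lv$height_m[e + 1] - lv$height_m[s]) * 100
    )
  })
}

#' Filter and band-classify inversion layers
#'
#' Keeps layers strong enough to matter for pollutant dilution and assigns
#' each to a height band by its *bottom*: layers with bottom below the
#' lower band floor (default 100 m) are discarded as surface-radiative;
#' bottoms in `[low_band[1], low_band[2])` are `"low"` (within the
#' boundary layer); bottoms at or above `low_band[2]` are `"upper"`
#' (typically subsidence inversions aloft). The intensity filter is strict:
#' a layer with `iv` exactly at `iv_min` is dropped.
#'
#' @param layers Layer tibble from [detect_inversions()].
#' @param iv_min Minimum intensity, degC per 100 m (strict `>`).
#' @param low_band,upper_band Height bands `(floor, ceiling)` in m for the
#'   low and upper classes; classification uses `z_bottom` only, so a layer
#'   straddling the band boundary is not split.
#' @return The surviving layers with a `band` column (`"low"`/`"upper"`).
#' @export
classify_inversions <- function(layers, iv_min = 0.1,
                                low_band = c(100, 1500),
                                upper_band = c(1500, 4000)) {
  stopifnot(low_band[1] < low_band[2], upper_band[1] < upper_band[2])
  layers |>
    dplyr::filter(.data$iv > iv_min, .data$z_bottom >= low_band[1]) |>
    dplyr::mutate(
      band = dplyr::if_else(.data$z_bottom < low_band[2], "low", "upper"))
}

#' Per-period summary of inversion occurrence over a haze episode
#'
#' Aggregates daily classified inversion layers over the pre-event, event
#' and post-event phases of one haze episode: days with at least one
#' low-band layer, days with multiple low-band layers, the range and mean
#' of low-band intensity, days with any upper-band layer, and days with no
#' sounding at all.
#'
#' @param daily_layers Classified layers for many days: the output of
#'   [classify_inversions()] with a `date` column added (zero rows for a
#'   sounding day with no surviving layer are fine).
#' @param event One row from [attach_windows()] (columns `pre_start` ...
#'   `post_end`).
#' @param sounding_dates Dates on which a sounding was actually available;
#'   days of the episode absent from it are reported as missing.
#' @return Tibble with one row per phase: `phase`, `n_days`,
#'   `n_sounding_days`, `n_missing_days`, `days_with_low`,
#'   `days_multi_low`, `iv_min`, `iv_max`, `iv_mean`, `days_with_upper`.
#' @export
episode_inversion_summary <- function(daily_layers, event, sounding_dates) {
  stopifnot(nrow(event) == 1)
  phases <- tibble::tibble(
    phase = c("pre", "haze", "post"),
    from = c(event$pre_start, event$start_date, event$post_start),
    to = c(event$pre_end, event$end_date, event$post_end)
  )
  purrr::pmap_dfr(phases, function(phase, from, to) {
    if (is.na(from)) {
      return(tibble::tibble(
        phase = phase, n_days = 0L, n_sounding_days = 0L,
        n_missing_days = 0L, days_with_low = 0L, days_multi_low = 0L,
        iv_min = NA_real_, iv_max = NA_real_, iv_mean = NA_real_,
        days_with_upper = 0L))
    }
    days <- seq(from, to, by = 1)
    have <- days %in% sounding_dates
    lay <- daily_layers[daily_layers$date %in% days, , drop = FALSE]
    low <- lay[lay$band == "low", , drop = FALSE]
    upper <- lay[lay$band == "upper", , drop = FALSE]
    low_per_day <- table(factor(as.character(low$date),
                                levels = as.character(days)))
    tibble::tibble(
      phase = phase,
      n_days = length(days),
      n_sounding_days = sum(have),
      n_missing_days = sum(!have),
      days_with_low = sum(low_per_day >= 1),
      days_multi_low = sum(low_per_day >= 2),
      iv_min = if (nrow(low)) min(low$iv) else NA_real_,
      iv_max = if (nrow(low)) max(low$iv) else NA_real_,
      iv_mean = if (nrow(low)) mean(low$iv) else NA_real_,
      days_with_upper = length(unique(upper$date))
    )
  })
}
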