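#' Default quality-control ranges for hourly station data
#'
#' Closed detectable-limit / plausible-range intervals per variable:
#' PM2.5 and PM10 3-1000 ug m^-3, temperature -5 to 50 degC, relative
#' humidity 0-100%, wind speed 0-50 m s^-1, wind direction 0-360 degrees,
#' rain 0-1000 mm h^-1, global radiation 0-1000 W m^-2. Values outside
#' these intervals are instrument artefacts rather than weather.
#'
#' @return Tibble with columns `variable`, `lower`, `upper`.
#' @export
#' @examples
#' qc_ranges()
qc_ranges <- function() {
  tibble::tribble(
    ~variable, ~lower, ~upper,
    "PM25",    3,      1000,
    "PM10",    3,      1000,
    "T",       -5,     50,
    "RH",      0,      100,
    "WS",      0,      50,
    "WD",      0,      360,
    "RN",      0,      1000,
    "GR",      0,      1000
  )
}

#' Flag hourly values outside their physical range
#'
#' Screens a long hourly series against closed per-variable intervals.
#' Out-of-range values are retained but flagged `out_of_range`, never
#' dropped; in-range values are flagged `valid`; `NA` values are flagged
#' `missing`. An optional exclusion list marks individual observations as
#' `visually_flagged` (manual removal of erratic values). Screening is
#' idempotent and never alters `value`.
#'
#' @param series Long hourly tibble with columns `station_id`, `variable`,
#'   `height_m`, `timestamp`, `value` and (optionally pre-existing)
#'   `qc_flag`.
#' @param ranges Range table as from [qc_ranges()].
#' @param exclusions Optional tibble of observations to flag manually,
#'   with columns `station_id`, `variable`, `timestamp`.
#' @param quiet Suppress the per-flag count message.
#' @return The series with `qc_flag` set for every row.
#' @export
screen_ranges <- function(series, ranges = qc_ranges(), exclusions = NULL,
                          quiet = FALSE) {
  if (!"qc_flag" %in% names(series)) series$qc_flag <- NA_character_
  check_series(series)
  unknown <- setdiff(unique(series$variable), ranges$variable)
  if (length(unknown)) {
    stop("no QC range configured for variable(s): ",
         paste(unknown, collapse = ", "))
  }
  out <- series |>
    dplyr::left_join(ranges, by = "variable") |>
    dplyr::mutate(
      qc_flag = dplyr::case_when(
        is.na(.data$value) ~ "missing",
        .data$value < .data$lower | .data$value > .data$upper ~
          "out_of_range",
        .default = "valid"
      )
    ) |>
    dplyr::select(-"lower", -"upper")
  if (!is.null(exclusions)) {
    key <- function(d) paste(d$station_id, d$variable, format(d$timestamp))
    hit <- key(out) %in% key(exclusions)
    out$qc_flag[hit & out$qc_flag != "missing"] <- "visually_flagged"
  }
  if (!quiet) {
    counts <- table(out$qc_flag)
    rlang::inform(paste0(
      "screen_ranges: ",
      paste(sprintf("%s=%d", names(counts), as.integer(counts)),
            collapse = ", ")))
  }
  out
}

#' Aggregate an hourly series to daily values
#'
#' Daily mean of usable hourly values inside a window of local-time hour
#' labels (hour `h` covers `(h-1, h]`; a full day is hours 1-24). A day's
#' value is reported only when at least `min_valid_fraction` of the window
#' hours are usable (flag `valid` or `filled`); otherwise it is `NA`. The
#' 50% default is inclusive: 12 usable hours out of 24 yield a mean, 11 do
#' not. Wind direction (`variable == "WD"`) is averaged as the direction of
#' the mean unit vector, reported in `[0, 360)`.
#'
#' @param series Long hourly tibble (see [screen_ranges()]).
#' @param window_hours Subset of `1:24`; e.g. `11:16` restricts global
#'   radiation to late-morning through mid-afternoon hours.
#' @param min_valid_fraction Minimum fraction of window hours that must be
#'   usable, inclusive.
#' @return Tibble with `station_id`, `variable`, `height_m`, `date`,
#'   `value`, `n_valid`, `valid_fraction`.
#' @export
aggregate_daily <- function(series, window_hours = 1:24,
                            min_valid_fraction = 0.5) {
  check_series(series)
  if (length(window_hours) == 0) stop("empty aggregation window")
  stopifnot(all(window_hours %in% 1:24))
  lab <- hour_label(series$timestamp)
  n_window <- length(window_hours)
  series |>
    dplyr::mutate(.date = lab$date, .hour = lab$hour) |>
    dplyr::filter(.data$.hour %in% window_hours) |>
    dplyr::group_by(.data$station_id, .data$variable, .data$height_m,
                    date = .data$.date) |>
    dplyr::summarise(
      n_valid = sum(.data$qc_flag %in% VALID_FLAGS & !is.na(.data$value)),
      value = {
        ok <- .data$qc_flag %in% VALID_FLAGS & !is.na(.data$value)
        if (sum(ok) >= min_valid_fraction * n_window) {
          if (.data$variable[1] == "WD") {
            circular_mean(.data$value[ok])
          } else {
            mean(.data$value[ok])
          }
        } else {
          NA_real_
        }
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(valid_fraction = .data$n_valid / n_window) |>
    dplyr::select("station_id", "variable", "height_m", "date", "value",
                  "n_valid", "valid_fraction")
}

# Direction of the mean unit vector, degrees in [0, 360).
circular_mean <- function(deg) {
  rad <- deg * pi / 180
  ang <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  (ang + 360) %% 360
}

#' Gap-fill a series by linear regression on a reference station
#'
#' Fits ordinary least squares `target ~ a + b * reference` on hours where
#' both series are valid, then replaces missing target hours that have a
#' valid reference value with the regression prediction, flagged `filled`.
#' Hours that were originally valid are never altered. Refuses to fill
#' (with a warning) when fewer than `min_pairs` paired valid hours exist.
#'
#' @param target,reference Long hourly tibbles for one variable each,
#'   aligned by `timestamp`.
#' @param min_pairs Minimum paired valid hours required to fit.
#' @param quiet Suppress the fitted-coefficients message.
#' @return The target series with gaps filled; the fitted `lm` object is
#'   attached as attribute `fit`.
#' @export
gap_fill_linear <- function(target, reference, min_pairs = 100,
                            quiet = FALSE) {
  check_series(target, "target")
  check_series(reference, "reference")
  ref <- reference |>
    dplyr::transmute(
      timestamp = .data$timestamp,
      ref_value = .data$value,
      ref_ok = .data$qc_flag %in% VALID_FLAGS & !is.na(.data$value))
  merged <- dplyr::left_join(target, ref, by = "timestamp")
  tgt_ok <- merged$qc_flag %in% VALID_FLAGS & !is.na(merged$value)
  pairs <- tgt_ok & merged$ref_ok
  if (sum(pairs) < min_pairs) {
    rlang::warn(sprintf(
      "gap_fill_linear: only %d paired valid hours (< %d); not filling",
      sum(pairs), min_pairs))
    return(target)
  }
  fit <- stats::lm(value ~ ref_value, data = merged[pairs, ])
  a <- stats::coef(fit)[[1]]
  b <- stats::coef(fit)[[2]]
  if (!quiet) {
    rlang::inform(sprintf(
      "gap_fill_linear: value = %.4g + %.4g * reference (R^2 = %.3f, n = %d)",
      a, b, summary(fit)$r.squared, sum(pairs)))
  }
  fill <- !tgt_ok & merged$ref_ok
  out <- target
  out$value[fill] <- a + b * merged$ref_value[fill]
  out$qc_flag[fill] <- "filled"
  attr(out, "fit") <- fit
  out
}

#' Daily mean of the hourly PM2.5/PM10 ratio
#'
#' Computes the hourly fine-to-coarse ratio where both PM series are valid
#' and PM10 is positive, then averages to daily values under the same
#' minimum-valid-fraction rule as [aggregate_daily()] (the fraction is
#' taken over the full 24-hour day). The daily value is the mean of hourly
#' ratios, not the ratio of daily means.
#'
#' @param pm25,pm10 Long hourly tibbles for the two size fractions at one
#'   station, aligned by `timestamp`.
#' @param min_valid_fraction Minimum fraction of the 24 hours with a
#'   computable ratio, inclusive.
#' @return Daily tibble as from [aggregate_daily()], `variable = "PM_RATIO"`.
#' @export
daily_ratio <- function(pm25, pm10, min_valid_fraction = 0.5) {
  check_series(pm25, "pm25")
  check_series(pm10, "pm10")
  coarse <- pm10 |>
    dplyr::transmute(
      timestamp = .data$timestamp,
      pm10_value = .data$value,
      pm10_ok = .data$qc_flag %in% VALID_FLAGS & !is.na(.data$value) &
        .data$value > 0)
  ratio <- pm25 |>
    dplyr::inner_join(coarse, by = "timestamp") |>
    dplyr::mutate(
      ok = .data$qc_flag %in% VALID_FLAGS & !is.na(.data$value) &
        .data$pm10_ok,
      value = dplyr::if_else(.data$ok, .data$value / .data$pm10_value,
                             NA_real_),
      qc_flag = dplyr::if_else(.data$ok, "valid", "missing"),
      variable = "PM_RATIO"
    ) |>
    dplyr::select("station_id", "variable", "height_m", "timestamp",
                  "value", "qc_flag")
  aggregate_daily(ratio, window_hours = 1:24,
                  min_valid_fraction = min_valid_fraction)
}
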