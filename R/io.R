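#' Read an hourly station-series CSV
#'
#' Strict reader for the long hourly layout used throughout the package:
#' columns `timestamp` (ISO 8601, local clock time), `station_id`,
#' `variable`, `height_m`, `value`. A configurable token marks missing
#' values; anything else non-numeric is an error.
#'
#' @param path File path.
#' @param na Missing-value token(s).
#' @param tz Timezone label applied to the clock times (the data carry no
#'   offsets; analysis is in fixed local time).
#' @return Long hourly tibble with `qc_flag` initialised to `"valid"` /
#'   `"missing"`.
#' @export
read_hourly_csv <- function(path, na = c("NA", ""), tz = "UTC") {
  raw <- readr::read_csv(
    path, na = na, show_col_types = FALSE,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      station_id = readr::col_character(),
      variable = readr::col_character(),
      height_m = readr::col_double(),
      value = readr::col_double()
    ))
  attr(raw$timestamp, "tzone") <- tz
  raw |>
    dplyr::mutate(qc_flag = dplyr::if_else(is.na(.data$value), "missing",
                                           "valid")) |>
    dplyr::select("station_id", "variable", "height_m", "timestamp",
                  "value", "qc_flag")
}

#' Write an hourly or daily series to CSV
#'
#' @param x Tibble to write.
#' @param path Destination path.
#' @return `x`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' Read a radiosonde sounding in Wyoming-archive text format
#'
#' Parses the fixed-width `PRES HGHT TEMP DWPT ...` table of the University
#' of Wyoming upper-air archive dialect (11 columns of 7 characters).
#' Heights in the archive are metres above mean sea level; supplying the
#' station elevation converts them to above-ground heights.
#'
#' @param path File path (plain text, one sounding).
#' @param station_elevation_m Station elevation, m MSL, subtracted from the
#'   archive heights.
#' @return Sounding tibble: `pressure_hpa`, `height_m` (AGL), `temp_c`,
#'   `dewpoint_c`, rows ordered by height.
#' @export
read_wyoming <- function(path, station_elevation_m = 0) {
  lines <- readLines(path)
  dashed <- grep("^-{10,}", lines)
  if (length(dashed) < 2) stop("not a Wyoming-format sounding: ", path)
  start <- dashed[length(dashed)] + 1
  body <- lines[start:length(lines)]
  body <- body[grepl("^\\s*[0-9]", body)]
  field <- function(line, i) {
    s <- substr(line, (i - 1) * 7 + 1, i * 7)
    v <- suppressWarnings(as.numeric(trimws(s)))
    v
  }
  out <- tibble::tibble(
    pressure_hpa = vapply(body, field, numeric(1), i = 1, USE.NAMES = FALSE),
    height_m = vapply(body, field, numeric(1), i = 2, USE.NAMES = FALSE) -
      station_elevation_m,
    temp_c = vapply(body, field, numeric(1), i = 3, USE.NAMES = FALSE),
    dewpoint_c = vapply(body, field, numeric(1), i = 4, USE.NAMES = FALSE)
  )
  out |>
    dplyr::filter(!is.na(.data$height_m)) |>
    dplyr::arrange(.data$height_m)
}

#' Read a sounding from a simple CSV
#'
#' Column-name-based alternative to [read_wyoming()]: expects
#' `pressure_hpa`, `height_m`, `temp_c` and optionally `dewpoint_c`.
#'
#' @inheritParams read_wyoming
#' @return Sounding tibble ordered by height.
#' @export
read_sounding_csv <- function(path, station_elevation_m = 0) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("pressure_hpa", "height_m", "temp_c") %in% names(out)))
  if (!"dewpoint_c" %in% names(out)) out$dewpoint_c <- NA_real_
  out$height_m <- out$height_m - station_elevation_m
  dplyr::arrange(out, .data$height_m)
}

#' Read satellite active-fire hotspots from CSV
#'
#' Reader for fire-detection point lists in the style of the MODIS global
#' monthly fire-location product (one detection per row). Only `latitude`,
#' `longitude` and `acq_date` are required; a `confidence` column is kept
#' when present.
#'
#' @param path File path.
#' @return Tibble with `latitude`, `longitude`, `acq_date` (Date) and
#'   optionally `confidence`.
#' @export
read_hotspots_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("latitude", "longitude", "acq_date") %in% names(out)))
  out$acq_date <- as.Date(out$acq_date)
  bad <- abs(out$latitude) > 90 | abs(out$longitude) > 180
  if (any(bad, na.rm = TRUE)) stop("hotspot coordinates out of range")
  keep <- intersect(c("latitude", "longitude", "acq_date", "confidence"),
                    names(out))
  out[keep]
}
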