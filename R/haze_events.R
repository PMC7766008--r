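#' Classify days as haze days from multi-station daily PM2.5
#'
#' A haze day is a day whose daily PM2.5 reaches the exceedance threshold
#' (inclusive, default the 50 ug m^-3 daily standard) at one station at
#' least. Days where every station is missing are marked indeterminate and
#' counted as non-haze.
#'
#' @param daily Per-station daily tibble with columns `station_id`, `date`,
#'   `value` (daily PM2.5, ug m^-3; `NA` = missing), e.g. from
#'   [aggregate_daily()].
#' @param threshold Exceedance threshold, ug m^-3, inclusive.
#' @return A haze calendar: tibble with one row per date of the continuous
#'   span covered, columns `date`, `haze_day` (logical), `n_exceeding`,
#'   `max_pm25`, `indeterminate` (all stations missing).
#' @export
detect_haze_days <- function(daily, threshold = 50) {
  stopifnot(all(c("station_id", "date", "value") %in% names(daily)))
  if (nrow(daily) == 0) stop("no station data supplied")
  per_day <- daily |>
    dplyr::group_by(date = .data$date) |>
    dplyr::summarise(
      n_exceeding = sum(!is.na(.data$value) & .data$value >= threshold),
      max_pm25 = if (all(is.na(.data$value))) NA_real_
                 else max(.data$value, na.rm = TRUE),
      indeterminate = all(is.na(.data$value)),
      .groups = "drop"
    )
  tibble::tibble(date = seq(min(per_day$date), max(per_day$date), by = 1)) |>
    dplyr::left_join(per_day, by = "date") |>
    dplyr::mutate(
      n_exceeding = dplyr::coalesce(.data$n_exceeding, 0L),
      indeterminate = dplyr::coalesce(.data$indeterminate, TRUE),
      haze_day = .data$n_exceeding > 0
    ) |>
    dplyr::select("date", "haze_day", "n_exceeding", "max_pm25",
                  "indeterminate")
}

#' Segment a haze calendar into maximal haze events
#'
#' A haze event is a maximal run of consecutive haze days. Events shorter
#' than `min_length_days` are discarded after segmentation. By default an
#' indeterminate (all-stations-missing) day breaks a run; with
#' `bridge_missing = TRUE` a single indeterminate day flanked by haze days
#' on both sides is carried within the run, which mirrors how a monitoring
#' gap inside an otherwise continuous event is usually treated.
#'
#' @param calendar Haze calendar from [detect_haze_days()].
#' @param min_length_days Minimum event length retained, days.
#' @param bridge_missing Carry isolated indeterminate days inside a run.
#' @return Tibble of events, chronologically ordered: `event_id`,
#'   `start_date`, `end_date`, `n_days`, `peak_value`, `peak_date`.
#' @export
segment_events <- function(calendar, min_length_days = 1,
                           bridge_missing = FALSE) {
  stopifnot(nrow(calendar) > 0,
            all(c("date", "haze_day") %in% names(calendar)))
  haze <- calendar$haze_day & !is.na(calendar$haze_day)
  if (bridge_missing && "indeterminate" %in% names(calendar)) {
    n <- length(haze)
    if (n >= 3) {
      mid <- 2:(n - 1)
      bridge <- calendar$indeterminate[mid] & haze[mid - 1] & haze[mid + 1]
      haze[mid][bridge] <- TRUE
    }
  }
  runs <- rle(haze)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_length_days
  if (!any(keep)) {
    return(tibble::tibble(
      event_id = integer(), start_date = as.Date(character()),
      end_date = as.Date(character()), n_days = integer(),
      peak_value = numeric(), peak_date = as.Date(character())))
  }
  purrr::map2_dfr(starts[keep], ends[keep], function(s, e) {
    days <- calendar[s:e, ]
    peak_i <- if ("max_pm25" %in% names(days) && any(!is.na(days$max_pm25))) {
      which.max(days$max_pm25)
    } else {
      NA_integer_
    }
    tibble::tibble(
      start_date = days$date[1],
      end_date = days$date[nrow(days)],
      n_days = nrow(days),
      peak_value = if (is.na(peak_i)) NA_real_ else days$max_pm25[peak_i],
      peak_date = if (is.na(peak_i)) as.Date(NA) else days$date[peak_i]
    )
  }) |>
    dplyr::mutate(event_id = dplyr::row_number(), .before = 1)
}

#' Attach pre- and post-event windows to haze events
#'
#' Adds fixed-length calendar windows immediately before and after each
#' event, labelling the phases of a haze episode (pre-event, event,
#' post-event). Windows are labels computed by date arithmetic; a zero
#' length yields an empty window (`NA` bounds).
#'
#' @param events Event tibble from [segment_events()].
#' @param pre_days,post_days Window lengths in days (non-negative).
#' @return The events with `pre_start`, `pre_end`, `post_start`,
#'   `post_end` columns added.
#' @export
#' @examples
#' ev <- tibble::tibble(event_id = 1L,
#'                      start_date = as.Date("2015-01-14"),
#'                      end_date = as.Date("2015-01-29"), n_days = 16L)
#' attach_windows(ev, pre_days = 7, post_days = 4)
attach_windows <- function(events, pre_days = 7, post_days = 4) {
  stopifnot(pre_days >= 0, post_days >= 0,
            all(c("start_date", "end_date") %in% names(events)))
  events |>
    dplyr::mutate(
      pre_start = if (pre_days > 0) .data$start_date - pre_days
                  else as.Date(NA),
      pre_end = if (pre_days > 0) .data$start_date - 1 else as.Date(NA),
      post_start = if (post_days > 0) .data$end_date + 1 else as.Date(NA),
      post_end = if (post_days > 0) .data$end_date + post_days
                 else as.Date(NA)
    )
}

# Phase label (pre/haze/post/NA) for a vector of dates against one
# windowed event row.
episode_phase <- function(dates, event) {
  dplyr::case_when(
    !is.na(event$pre_start) & dates >= event$pre_start &
      dates <= event$pre_end ~ "pre",
    dates >= event$start_date & dates <= event$end_date ~ "haze",
    !is.na(event$post_start) & dates >= event$post_start &
      dates <= event$post_end ~ "post",
    .default = NA_character_
  )
}
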