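# Shared internal helpers.

#' @importFrom rlang .data
NULL

# Map timestamps to the 1-24 local-time hour-label convention: hour h covers
# (h-1, h], so a stamp at exactly midnight is hour 24 of the *previous*
# calendar day. Timestamps are POSIXct interpreted in their own timezone.
hour_label <- function(timestamp) {
  h <- as.integer(format(timestamp, "%H"))
  m <- as.integer(format(timestamp, "%M"))
  # sub-hourly stamps round up to the covering hour label
  h <- ifelse(m > 0, h + 1L, h)
  date <- as.Date(format(timestamp, "%Y-%m-%d"))
  midnight <- h == 0L | h == 24L
  list(
    date = dplyr::if_else(h == 0L, date - 1L, date),
    hour = ifelse(midnight, 24L, h)
  )
}

# Hourly timestamp sequence covering n_days days starting at `start` (Date),
# stamped at hours 01:00 ... 24:00 (= 00:00 next day) local time.
hourly_stamps <- function(start, n_days) {
  as.POSIXct(as.character(start), tz = "UTC") +
    3600 * seq_len(24 * n_days)
}

# Validate the long hourly-series layout used across the package.
check_series <- function(series, arg = "series") {
  need <- c("station_id", "variable", "height_m", "timestamp", "value",
            "qc_flag")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    stop(sprintf("`%s` lacks column(s): %s", arg,
                 paste(miss, collapse = ", ")))
  }
  invisible(series)
}

# Flags counted as usable observations.
VALID_FLAGS <- c("valid", "filled")
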