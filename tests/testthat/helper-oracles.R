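# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: the stability oracle locates roots of the
# self-consistency residual on a dense 1/L grid instead of iterating; the
# event oracle is a day-by-day scan; the grid oracle is a per-point loop.

# Brute-force Obukhov oracle: root of r(inv) = inv - 1/L_implied(inv) on a
# dense grid over [-1, 1] m^-1, refined by uniroot. Among multiple roots on
# the side matching sign(dthv), the one closest to neutral is the branch a
# neutral-started iteration reaches. Returns list(L, found).
oracle_obukhov <- function(U, dthv, tv_mean, z_u = 50, z_t = c(2, 50),
                           z0 = 0.25, k = 0.4, g = 9.81, n_grid = 80001,
                           inv_max = 2) {
  implied_inv <- function(inv) {
    us <- k * U / (log(z_u / z0) - psi_m(z_u * inv) + psi_m(z0 * inv))
    ts <- k * dthv /
      (log(z_t[2] / z_t[1]) - psi_h(z_t[2] * inv) + psi_h(z_t[1] * inv))
    k * g * ts / (tv_mean * us^2)
  }
  inv <- seq(-inv_max, inv_max, length.out = n_grid)
  inv <- inv[sign(inv) == sign(dthv)]
  r <- inv - implied_inv(inv)
  ok <- is.finite(r)
  inv <- inv[ok]
  r <- r[ok]
  flips <- which(r[-1] * r[-length(r)] < 0)
  if (!length(flips)) return(list(L = NA_real_, found = FALSE))
  # root nearest neutral
  i <- flips[which.min(pmin(abs(inv[flips]), abs(inv[flips + 1])))]
  root <- stats::uniroot(function(x) x - implied_inv(x),
                         c(inv[i], inv[i + 1]), tol = 1e-13)$root
  list(L = 1 / root, found = TRUE)
}

# Build a dry-air solver input whose virtual-potential-temperature
# difference between z_t heights equals `dthv` exactly (to 1e-12), using
# only the package's thermodynamic primitives.
sample_with_dthv <- function(U, dthv, t1_c = 25, p_sfc = 1010,
                             z_t = c(2, 50), const = met_constants()) {
  t2_c <- t1_c
  for (i in 1:25) {
    t_mean_k <- (t1_c + t2_c) / 2 + 273.15
    p1 <- pressure_at_height(p_sfc, z_t[1], t_mean_k, const$g)
    p2 <- pressure_at_height(p_sfc, z_t[2], t_mean_k, const$g)
    thv1 <- virtual_potential_temperature(t1_c + 273.15, p1, const$p_ref)
    t2_new <- (thv1 + dthv) / (const$p_ref / p2)^0.2854 - 273.15
    if (abs(t2_new - t2_c) < 1e-13) break
    t2_c <- t2_new
  }
  tibble::tibble(U = U, T1 = t1_c, T2 = t2_c, RH = 0, p_sfc = p_sfc)
}

# Mean virtual temperature the solver will see for a dry two-level sample.
tv_mean_of <- function(sample) {
  (sample$T1 + sample$T2) / 2 + 273.15
}

# Naive day-by-day scan segmentation of a logical haze vector.
scan_events <- function(haze, dates) {
  out <- list()
  i <- 1
  n <- length(haze)
  while (i <= n) {
    if (isTRUE(haze[i])) {
      j <- i
      while (j < n && isTRUE(haze[j + 1])) j <- j + 1
      out[[length(out) + 1]] <- tibble::tibble(
        start_date = dates[i], end_date = dates[j],
        n_days = as.integer(j - i + 1))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  dplyr::bind_rows(out)
}

# Per-point loop count of hotspots per (phase, cell), half-open cells.
loop_grid_count <- function(points, event, domain, cell) {
  total <- 0L
  for (i in seq_len(nrow(points))) {
    lon <- points$longitude[i]
    lat <- points$latitude[i]
    d <- points$acq_date[i]
    in_dom <- lon >= domain[1] && lon < domain[2] &&
      lat >= domain[3] && lat < domain[4]
    in_per <- (d >= event$pre_start && d <= event$pre_end) ||
      (d >= event$start_date && d <= event$end_date) ||
      (d >= event$post_start && d <= event$post_end)
    if (in_dom && in_per) total <- total + 1L
  }
  total
}

# Long hourly series builder for station-data tests: one station/variable,
# hour labels 1..24 on consecutive days.
make_series <- function(values, variable = "PM25", station = "S1",
                        height = 3, start = as.Date("2017-12-13"),
                        qc = NULL) {
  n_days <- ceiling(length(values) / 24)
  ts <- hazemet:::hourly_stamps(start, n_days)[seq_along(values)]
  tibble::tibble(
    station_id = station, variable = variable, height_m = height,
    timestamp = ts, value = values,
    qc_flag = if (is.null(qc)) ifelse(is.na(values), "missing", "valid")
              else qc)
}
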