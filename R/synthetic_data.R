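#' Describe a synthetic cold-surge haze episode
#'
#' Collects the parameters of the synthetic episode generator. The defaults
#' describe a wintertime cold-surge haze episode of the kind seen in
#' Greater Bangkok: a 6-day pre-event phase, an 8-day haze event and a
#' 5-day post-event phase; a surge arriving late in the pre-phase that
#' drops daily temperature by ~9.5 degC and relative humidity by ~29
#' percentage points within a day, with winds more than doubling while the
#' surge is active and a gradual multi-day recovery; daily PM2.5 around
#' 35 ug m^-3 outside the event, elevated by 30 ug m^-3 during it (clearing
#' the 50 ug m^-3 haze-day threshold), with a night/early-morning diurnal
#' peak; and a fine-to-coarse ratio near 0.8 typical of haze dominated by
#' local anthropogenic emissions.
#'
#' @param n_pre,n_haze,n_post Phase lengths, days (each >= 1).
#' @param start_date First day of the episode.
#' @param cold_surge_day 1-based episode day on which the surge front
#'   arrives.
#' @param surge_recovery_days e-folding time of the post-surge relaxation,
#'   days.
#' @param t_base,t_diurnal_amp Daily-mean temperature and diurnal
#'   half-amplitude, degC.
#' @param rh_base,rh_diurnal_amp Relative humidity baseline and diurnal
#'   half-amplitude, percent.
#' @param ws_base,ws_diurnal_amp Wind speed baseline and diurnal
#'   half-amplitude at 50 m, m s^-1.
#' @param dt_surge,drh_surge Peak surge drops in temperature (degC,
#'   negative) and relative humidity (percentage points, negative).
#' @param ws_surge_mult Wind-speed multiplier while the surge is active.
#' @param lapse_offset_amp Half-range of the 2 m - 50 m temperature
#'   contrast, degC: positive (superadiabatic) by day, negative (stable) by
#'   night, so both stability branches occur. The default 1.5 degC exceeds
#'   the ~0.47 degC adiabatic increment over 48 m, so afternoons are
#'   genuinely convective and nights genuinely stable.
#' @param gr_peak Clear-sky noon global radiation, W m^-2.
#' @param cloudy_pre_factor Radiation scaling on pre-surge (cloudier) days.
#' @param pm_base,pm_haze_elevation Daily-mean PM2.5 outside the event and
#'   its elevation during it, ug m^-3.
#' @param pm_diurnal_amp Relative amplitude of the PM2.5 diurnal cycle
#'   (peak at night/early morning, trough in the afternoon).
#' @param ratio Target PM2.5/PM10 ratio.
#' @param n_stations Number of PM stations sharing the regional signal.
#' @param sigma Named list of Gaussian noise standard deviations per
#'   variable (independent across hours).
#' @param outages Optional tibble of block outages to punch into the PM
#'   series: columns `station_id`, `variable`, `start_hour` (1-based index
#'   into the episode), `n_hours`.
#' @param seed Integer seed; generated data are reproducible bit for bit.
#' @return A list of class `episode_scenario`.
#' @export
episode_scenario <- function(n_pre = 6, n_haze = 8, n_post = 5,
                             start_date = as.Date("2017-12-13"),
                             cold_surge_day = 5,
                             surge_recovery_days = 4,
                             t_base = 30, t_diurnal_amp = 3,
                             rh_base = 74, rh_diurnal_amp = 8,
                             ws_base = 1.5, ws_diurnal_amp = 0.5,
                             dt_surge = -9.5, drh_surge = -29,
                             ws_surge_mult = 2.5,
                             lapse_offset_amp = 1.5,
                             gr_peak = 800, cloudy_pre_factor = 0.5,
                             pm_base = 35, pm_haze_elevation = 30,
                             pm_diurnal_amp = 0.4, ratio = 0.8,
                             n_stations = 2,
                             sigma = list(t = 0.3, rh = 2, ws = 0.3,
                                          gr = 20, pm = 5, pm10 = 5,
                                          p = 0.3),
                             outages = NULL, seed = 42L) {
  stopifnot(n_pre >= 1, n_haze >= 1, n_post >= 1,
            all(unlist(sigma) >= 0), surge_recovery_days > 0,
            n_stations >= 1, ratio > 0)
  sc <- as.list(environment())
  sc$start_date <- as.Date(start_date)
  sc$n_days <- n_pre + n_haze + n_post
  structure(sc, class = "episode_scenario")
}

# Surge response shape at time t (days since surge onset): linear drop over
# the first day, then exponential relaxation back to zero.
surge_shape <- function(t, recovery) {
  ifelse(t < 0, 0, ifelse(t < 1, t, exp(-(t - 1) / recovery)))
}

# Wind-surge shape: full strength for the first two active days, then decay.
surge_wind_shape <- function(t, recovery) {
  ifelse(t < 0, 0, ifelse(t < 2, 1, exp(-(t - 2) / recovery)))
}

#' Generate hourly tower and surface series for a synthetic episode
#'
#' Builds the hourly meteorological series a 100-m mast would record over
#' the episode: temperature at 2 m and 50 m, wind speed at 50 m and 100 m,
#' near-surface relative humidity, global radiation, rain and surface
#' pressure. Each series is a sinusoidal diurnal cycle plus the cold-surge
#' step-and-recovery trend plus independent seeded Gaussian noise. The
#' 50-m temperature is the 2-m temperature minus a lapse offset that is
#' positive by day and negative by night, so hourly stability spans both
#' the unstable and stable branches; global radiation follows a clear-sky
#' half-sine (scaled down on cloudy pre-surge days); the 100-m wind is the
#' 50-m wind scaled by the neutral logarithmic profile.
#'
#' @param scenario An [episode_scenario()].
#' @return Long hourly tibble (`station_id = "TW1"`) with variables `T`
#'   (heights 2 and 50), `WS` (50 and 100), `RH`, `GR`, `RN`, `PSFC`.
#'   The scenario is attached as attribute `scenario`, and the noiseless
#'   daily-mean 2-m temperature trend as attribute `truth_daily_t2`.
#' @export
gen_tower_series <- function(scenario) {
  stopifnot(inherits(scenario, "episode_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  ts <- hourly_stamps(sc$start_date, sc$n_days)
  n <- length(ts)
  hour <- rep(1:24, sc$n_days)
  day <- rep(seq_len(sc$n_days), each = 24)
  # days since surge onset at each hour (surge hits at the start of that day)
  t_surge <- (day - sc$cold_surge_day) + (hour - 0.5) / 24
  s <- surge_shape(t_surge, sc$surge_recovery_days)
  sw <- surge_wind_shape(t_surge, sc$surge_recovery_days)

  diurnal <- function(amp, peak_hour) amp * cos(2 * pi * (hour - peak_hour) / 24)
  t2 <- sc$t_base + diurnal(sc$t_diurnal_amp, 15) + sc$dt_surge * s +
    stats::rnorm(n, 0, sc$sigma$t)
  # day/night lapse contrast: unstable afternoons, stable nights
  offset <- sc$lapse_offset_amp * sin(2 * pi * (hour - 9.5) / 24)
  t50 <- t2 - offset + stats::rnorm(n, 0, sc$sigma$t / 2)
  rh <- sc$rh_base + diurnal(sc$rh_diurnal_amp, 5) + sc$drh_surge * s +
    stats::rnorm(n, 0, sc$sigma$rh)
  rh <- pmin(pmax(rh, 1), 100)
  ws50 <- (sc$ws_base + diurnal(sc$ws_diurnal_amp, 14)) *
    (1 + (sc$ws_surge_mult - 1) * sw) + stats::rnorm(n, 0, sc$sigma$ws)
  ws50 <- pmax(ws50, 0.2)
  ws100 <- ws50 * log(100 / 0.25) / log(50 / 0.25) +
    stats::rnorm(n, 0, sc$sigma$ws / 2)
  gr_clear <- ifelse(hour > 6 & hour <= 18,
                     sc$gr_peak * sin(pi * (hour - 6) / 12), 0)
  cloud <- ifelse(day < sc$cold_surge_day, sc$cloudy_pre_factor, 1)
  gr <- gr_clear * cloud +
    ifelse(gr_clear > 0, stats::rnorm(n, 0, sc$sigma$gr), 0)
  gr <- pmax(gr, 0)
  rn <- rep(0, n)
  psfc <- 1010 + 1.5 * cos(2 * pi * (hour - 10) / 12) +
    stats::rnorm(n, 0, sc$sigma$p)

  long <- function(variable, height, values) {
    tibble::tibble(station_id = "TW1", variable = variable,
                   height_m = height, timestamp = ts, value = values,
                   qc_flag = "valid")
  }
  out <- dplyr::bind_rows(
    long("T", 2, t2), long("T", 50, t50),
    long("WS", 50, ws50), long("WS", 100, ws100),
    long("RH", 2, rh), long("GR", 2, gr), long("RN", 2, rn),
    long("PSFC", 2, psfc)
  )
  truth <- tibble::tibble(
    date = sc$start_date + seq_len(sc$n_days) - 1,
    t2_mean = sc$t_base + sc$dt_surge *
      vapply(seq_len(sc$n_days), function(d) {
        mean(surge_shape((d - sc$cold_surge_day) + (1:24 - 0.5) / 24,
                         sc$surge_recovery_days))
      }, numeric(1))
  )
  attr(out, "scenario") <- sc
  attr(out, "truth_daily_t2") <- truth
  out
}

#' Pivot a tower series to the solver's wide hourly layout
#'
#' @param series Long tower tibble from [gen_tower_series()] (or the same
#'   layout read from file).
#' @param z_u Wind height to expose as `U`, m.
#' @param z_t Two temperature heights to expose as `T1`, `T2`, m.
#' @return Wide tibble with `timestamp`, `U`, `T1`, `T2`, `RH`, `p_sfc`,
#'   ready for [solve_obukhov()]. Values flagged neither valid nor filled
#'   become `NA`.
#' @export
tower_wide <- function(series, z_u = 50, z_t = c(2, 50)) {
  check_series(series)
  pick <- function(variable, height) {
    series |>
      dplyr::filter(.data$variable == !!variable,
                    .data$height_m == !!height) |>
      dplyr::transmute(
        timestamp = .data$timestamp,
        value = dplyr::if_else(.data$qc_flag %in% VALID_FLAGS,
                               .data$value, NA_real_))
  }
  out <- pick("WS", z_u) |> dplyr::rename(U = "value")
  out <- dplyr::left_join(out, pick("T", z_t[1]), by = "timestamp") |>
    dplyr::rename(T1 = "value")
  out <- dplyr::left_join(out, pick("T", z_t[2]), by = "timestamp") |>
    dplyr::rename(T2 = "value")
  rh <- pick("RH", unique(series$height_m[series$variable == "RH"])[1])
  out <- dplyr::left_join(out, rh, by = "timestamp") |>
    dplyr::rename(RH = "value")
  ps <- series[series$variable == "PSFC", , drop = FALSE]
  if (nrow(ps)) {
    out <- dplyr::left_join(
      out, dplyr::transmute(ps, timestamp = .data$timestamp,
                            p_sfc = .data$value),
      by = "timestamp")
  }
  out
}

#' Generate hourly PM2.5 and PM10 series for a synthetic episode
#'
#' Hourly fine-particle concentrations at `n_stations` stations sharing the
#' episode signal: each day's mean sits at the baseline, elevated by the
#' configured amount during the haze phase, modulated by a diurnal factor
#' (mean one) that peaks at night/early morning and dips in the afternoon.
#' PM10 is PM2.5 divided by the target fine-to-coarse ratio, plus noise.
#' Optional block outages knock out consecutive hours to exercise the
#' minimum-valid-fraction rule.
#'
#' @param scenario An [episode_scenario()].
#' @return Long hourly tibble with variables `PM25` and `PM10` at stations
#'   `"S1"`, `"S2"`, ... Attribute `truth_haze_dates` lists the dates of
#'   the haze phase; attribute `scenario` carries the input.
#' @export
gen_pm_series <- function(scenario) {
  stopifnot(inherits(scenario, "episode_scenario"))
  sc <- scenario
  set.seed(sc$seed + 1L)
  ts <- hourly_stamps(sc$start_date, sc$n_days)
  n <- length(ts)
  hour <- rep(1:24, sc$n_days)
  day <- rep(seq_len(sc$n_days), each = 24)
  in_haze <- day > sc$n_pre & day <= sc$n_pre + sc$n_haze
  day_mean <- sc$pm_base + sc$pm_haze_elevation * in_haze
  diurnal <- 1 + sc$pm_diurnal_amp * cos(2 * pi * (hour - 4) / 24)
  out <- purrr::map_dfr(seq_len(sc$n_stations), function(st) {
    pm25 <- day_mean * diurnal + stats::rnorm(n, 0, sc$sigma$pm)
    pm25 <- pmax(pm25, 3)
    pm10 <- pm25 / sc$ratio + stats::rnorm(n, 0, sc$sigma$pm10)
    pm10 <- pmax(pm10, pm25)   # coarse total never below the fine fraction
    dplyr::bind_rows(
      tibble::tibble(station_id = paste0("S", st), variable = "PM25",
                     height_m = 3, timestamp = ts, value = pm25,
                     qc_flag = "valid"),
      tibble::tibble(station_id = paste0("S", st), variable = "PM10",
                     height_m = 3, timestamp = ts, value = pm10,
                     qc_flag = "valid")
    )
  })
  if (!is.null(sc$outages)) {
    for (i in seq_len(nrow(sc$outages))) {
      o <- sc$outages[i, ]
      idx <- which(out$station_id == o$station_id &
                     out$variable == o$variable)
      hit <- idx[seq(o$start_hour, length.out = o$n_hours)]
      hit <- hit[!is.na(hit)]
      out$value[hit] <- NA_real_
      out$qc_flag[hit] <- "missing"
    }
  }
  attr(out, "scenario") <- sc
  attr(out, "truth_haze_dates") <-
    sc$start_date + seq(sc$n_pre, length.out = sc$n_haze)
  out
}

#' Describe synthetic sounding profiles with implanted inversions
#'
#' @param layers List with one element per day, each a tibble (possibly
#'   zero-row) with columns `z_bottom`, `z_top`, `iv` (degC per 100 m,
#'   positive) describing the inversion layers to implant. Layers within a
#'   day must be disjoint with a positive gap.
#' @param lapse_c_per_km Background cooling rate outside implanted layers.
#' @param spacing_m Regular reporting-level spacing; layer endpoints are
#'   always included as levels.
#' @param t_sfc_c Surface temperature at release time, degC.
#' @param top Profile ceiling, m.
#' @param p_sfc Surface pressure, hPa.
#' @param seed Integer seed (used by [random_sounding_scenario()]).
#' @return A list of class `sounding_scenario`.
#' @export
sounding_scenario <- function(layers, lapse_c_per_km = 6.5,
                              spacing_m = 100, t_sfc_c = 24, top = 4000,
                              p_sfc = 1010, seed = 42L) {
  stopifnot(is.list(layers), lapse_c_per_km > 0, spacing_m > 0)
  for (d in seq_along(layers)) {
    lay <- layers[[d]]
    if (nrow(lay) == 0) next
    stopifnot(all(lay$iv > 0), all(lay$z_top > lay$z_bottom),
              all(lay$z_bottom >= 0), all(lay$z_top <= top))
    lay <- lay[order(lay$z_bottom), ]
    if (nrow(lay) > 1 &&
        any(lay$z_bottom[-1] <= lay$z_top[-nrow(lay)])) {
      stop("implanted layers overlap or touch on day ", d)
    }
    layers[[d]] <- lay
  }
  structure(list(layers = layers, lapse_c_per_km = lapse_c_per_km,
                 spacing_m = spacing_m, t_sfc_c = t_sfc_c, top = top,
                 p_sfc = p_sfc, seed = seed, n_days = length(layers)),
            class = "sounding_scenario")
}

#' Randomly implanted sounding scenario
#'
#' Draws, for each day, 0-3 disjoint inversion layers with bottoms between
#' 50 and 3400 m, depths of 100-500 m and intensities between 0.02 and
#' 2.5 degC per 100 m — spanning the sub-threshold, low-band and
#' upper-band regimes so that detection, filtering and band assignment are
#' all exercised.
#'
#' @param n_days Number of daily profiles.
#' @param seed Integer seed.
#' @param ... Passed to [sounding_scenario()].
#' @return A `sounding_scenario`.
#' @export
random_sounding_scenario <- function(n_days, seed = 42L, ...) {
  set.seed(seed)
  layers <- lapply(seq_len(n_days), function(d) {
    k <- sample(0:3, 1)
    if (k == 0) {
      return(tibble::tibble(z_bottom = numeric(), z_top = numeric(),
                            iv = numeric()))
    }
    repeat {
      bottom <- sort(stats::runif(k, 50, 3400))
      depth <- stats::runif(k, 100, 500)
      top_z <- bottom + depth
      if (k == 1 || all(bottom[-1] > top_z[-k] + 10)) break
    }
    tibble::tibble(z_bottom = bottom, z_top = top_z,
                   iv = stats::runif(k, 0.02, 2.5))
  })
  sounding_scenario(layers, seed = seed, ...)
}

#' Generate one synthetic sounding profile
#'
#' Piecewise-linear temperature profile: the background lapse rate applies
#' outside implanted layers, and within each implanted layer temperature
#' rises at the implanted intensity. Levels sit at the regular spacing plus
#' every layer endpoint, so detection can recover implants exactly.
#' Pressure decreases hydrostatically from the surface.
#'
#' @param scenario A [sounding_scenario()].
#' @param day 1-based day index into `scenario$layers`.
#' @return Sounding tibble (`pressure_hpa`, `height_m`, `temp_c`,
#'   `dewpoint_c`) with the day's implanted layers attached as attribute
#'   `truth_layers`.
#' @export
gen_sounding <- function(scenario, day) {
  stopifnot(inherits(scenario, "sounding_scenario"),
            day >= 1, day <= scenario$n_days)
  lay <- scenario$layers[[day]]
  z <- sort(unique(c(seq(0, scenario$top, by = scenario$spacing_m),
                     lay$z_bottom, lay$z_top)))
  # slope (degC per m) on each segment between consecutive levels
  slope_at <- function(z_lo, z_hi) {
    mid <- (z_lo + z_hi) / 2
    inside <- nrow(lay) > 0 && any(mid > lay$z_bottom & mid < lay$z_top)
    if (inside) {
      i <- which(mid > lay$z_bottom & mid < lay$z_top)[1]
      lay$iv[i] / 100
    } else {
      -scenario$lapse_c_per_km / 1000
    }
  }
  temp <- numeric(length(z))
  temp[1] <- scenario$t_sfc_c
  for (i in seq_along(z)[-1]) {
    temp[i] <- temp[i - 1] + slope_at(z[i - 1], z[i]) * (z[i] - z[i - 1])
  }
  t_mean_k <- mean(temp) + 273.15
  out <- tibble::tibble(
    pressure_hpa = pressure_at_height(scenario$p_sfc, z, t_mean_k),
    height_m = z,
    temp_c = temp,
    dewpoint_c = temp - 5
  )
  attr(out, "truth_layers") <- lay
  out
}

#' Generate a similarity-consistent tower sample for a known Obukhov length
#'
#' Inverts the flux-profile relations: fixes the true Obukhov length,
#' derives the friction velocity from the wind-profile equation at
#' `zeta = z_u / L_true`, the temperature scale from the definition of `L`,
#' and the implied two-level virtual-potential-temperature difference from
#' the temperature-profile equation — then emits the wind speed and level
#' temperatures (dry air, so virtual equals actual temperature) that
#' reproduce them. Feeding the sample to [solve_obukhov()] must recover
#' `L_true`; this is the package's parameter-recovery harness.
#'
#' @param L_true True Obukhov length, m (|L| > 1; `zeta = z_u/L_true` must
#'   lie within the similarity validity range `[-5, 5]`).
#' @param U_scale Wind speed at `z_u`, m s^-1.
#' @param const [met_constants()].
#' @param z_u Wind height, m.
#' @param z_t Temperature heights, m.
#' @param t1_c Lower-level air temperature, degC.
#' @param p_sfc Surface pressure, hPa.
#' @return One-row tibble with `U`, `T1`, `T2`, `RH` (0), `p_sfc`, and
#'   attributes `L_true`, `u_star`, `theta_star`.
#' @export
gen_most_consistent_sample <- function(L_true, U_scale = 5,
                                       const = met_constants(),
                                       z_u = 50, z_t = c(2, 50),
                                       t1_c = 25, p_sfc = 1010) {
  stopifnot(abs(L_true) > 1)
  zeta_u <- z_u / L_true
  if (abs(zeta_u) > 5) {
    stop("zeta = z_u/L_true outside similarity validity range [-5, 5]")
  }
  k <- const$k
  log_u <- log(z_u / const$z0)
  log_t <- log(z_t[2] / z_t[1])
  u_star <- k * U_scale /
    (log_u - psi_m(zeta_u) + psi_m(const$z0 / L_true))
  t2_c <- t1_c
  for (i in 1:8) {   # small fixed point: T2 <-> pressures/Tv mean
    t_mean_k <- (t1_c + t2_c) / 2 + 273.15
    p1 <- pressure_at_height(p_sfc, z_t[1], t_mean_k, const$g)
    p2 <- pressure_at_height(p_sfc, z_t[2], t_mean_k, const$g)
    tv1 <- t1_c + 273.15              # dry air
    tv2 <- t2_c + 273.15
    theta_star <- (tv1 + tv2) / 2 * u_star^2 / (k * const$g * L_true)
    dthv <- theta_star *
      (log_t - psi_h(z_t[2] / L_true) + psi_h(z_t[1] / L_true)) / k
    thv1 <- virtual_potential_temperature(tv1, p1, const$p_ref)
    thv2 <- thv1 + dthv
    t2_new <- thv2 / (const$p_ref / p2)^KAPPA - 273.15
    if (abs(t2_new - t2_c) < 1e-12) {
      t2_c <- t2_new
      break
    }
    t2_c <- t2_new
  }
  out <- tibble::tibble(U = U_scale, T1 = t1_c, T2 = t2_c, RH = 0,
                        p_sfc = p_sfc)
  attr(out, "L_true") <- L_true
  attr(out, "u_star") <- u_star
  attr(out, "theta_star") <- theta_star
  out
}

#' Generate a synthetic active-fire point cloud
#'
#' Uniform random hotspots over a domain with dates drawn from the phases
#' of a windowed haze event, weighted so the haze phase is busiest —
#' enough structure to exercise period assignment and gridding.
#'
#' @param n Number of points.
#' @param event One windowed event row from [attach_windows()].
#' @param domain `c(lon_min, lon_max, lat_min, lat_max)`, degrees.
#' @param phase_weights Sampling weights for (pre, haze, post) dates.
#' @param seed Integer seed.
#' @return Hotspot tibble: `latitude`, `longitude`, `acq_date`,
#'   `confidence`.
#' @export
gen_hotspots <- function(n, event, domain,
                         phase_weights = c(1, 3, 1), seed = 42L) {
  set.seed(seed)
  dates <- c(
    if (!is.na(event$pre_start)) seq(event$pre_start, event$pre_end, by = 1),
    seq(event$start_date, event$end_date, by = 1),
    if (!is.na(event$post_start)) seq(event$post_start, event$post_end,
                                      by = 1))
  phase <- episode_phase(dates, event)
  w <- phase_weights[match(phase, c("pre", "haze", "post"))]
  tibble::tibble(
    latitude = stats::runif(n, domain[3], domain[4]),
    longitude = stats::runif(n, domain[1], domain[2]),
    acq_date = sample(dates, n, replace = TRUE, prob = w / sum(w)),
    confidence = sample(30:100, n, replace = TRUE)
  )
}
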