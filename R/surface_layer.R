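#' Physical constants for surface-layer calculations
#'
#' Bundles the constants used by the Monin-Obukhov solver. The defaults are
#' the conventional von Karman constant, standard gravity, a roughness length
#' of 0.25 m (Davenport terrain class 5, "rough" — sparsely built suburban
#' land with ponds and paddy fields), and the 1000 hPa reference pressure for
#' potential temperature.
#'
#' @param k Von Karman constant (dimensionless).
#' @param g Gravitational acceleration, m s^-2.
#' @param z0 Aerodynamic roughness length, m.
#' @param p_ref Reference pressure for potential temperature, hPa.
#' @return A list of class `met_constants`.
#' @export
#' @examples
#' met_constants()
met_constants <- function(k = 0.4, g = 9.81, z0 = 0.25, p_ref = 1000) {
  stopifnot(k > 0, g > 0, z0 > 0, p_ref > 0)
  structure(list(k = k, g = g, z0 = z0, p_ref = p_ref),
            class = "met_constants")
}

# Dry-air gas constant, J kg^-1 K^-1
R_DRY <- 287.05
# Poisson exponent R_d / c_p for potential temperature
KAPPA <- 0.2854

#' Saturation vapour pressure over liquid water
#'
#' Bolton's (1980) fit, accurate to ~0.1% between -35 and +35 degC.
#'
#' @param temp_c Air temperature, degC.
#' @return Saturation vapour pressure, hPa.
#' @export
saturation_vapour_pressure <- function(temp_c) {
  6.112 * exp(17.67 * temp_c / (temp_c + 243.5))
}

#' Specific humidity from temperature, relative humidity and pressure
#'
#' @param temp_c Air temperature, degC.
#' @param rh Relative humidity, percent (0-100).
#' @param pressure_hpa Air pressure, hPa.
#' @return Specific humidity, kg kg^-1.
#' @export
specific_humidity <- function(temp_c, rh, pressure_hpa) {
  e <- (rh / 100) * saturation_vapour_pressure(temp_c)
  if (any(pressure_hpa <= e, na.rm = TRUE)) {
    stop("vapour pressure exceeds total pressure: non-physical input")
  }
  0.622 * e / (pressure_hpa - 0.378 * e)
}

#' Virtual temperature
#'
#' Temperature of dry air with the same density as the given moist air:
#' `Tv = T * (1 + 0.608 q)` with specific humidity `q` derived from relative
#' humidity and pressure. Dry air (`rh = 0`) returns the input temperature in
#' kelvin unchanged.
#'
#' @inheritParams specific_humidity
#' @return Virtual temperature, K.
#' @export
#' @examples
#' virtual_temperature(30, 100, 1013.25)
virtual_temperature <- function(temp_c, rh, pressure_hpa) {
  q <- specific_humidity(temp_c, rh, pressure_hpa)
  (temp_c + 273.15) * (1 + 0.608 * q)
}

#' Pressure at height by hydrostatic adjustment
#'
#' Isothermal hypsometric reduction `p(z) = p_sfc * exp(-g z / (R_d T))`
#' using a layer-mean temperature.
#'
#' @param p_sfc Surface pressure, hPa.
#' @param z Height above the surface, m (non-negative).
#' @param t_mean_k Layer-mean temperature, K.
#' @param g Gravitational acceleration, m s^-2.
#' @return Pressure at height `z`, hPa.
#' @export
pressure_at_height <- function(p_sfc, z, t_mean_k, g = 9.81) {
  stopifnot(all(z >= 0))
  p_sfc * exp(-g * z / (R_DRY * t_mean_k))
}

#' Virtual potential temperature
#'
#' @param tv_k Virtual temperature, K.
#' @param pressure_hpa Pressure at the measurement height, hPa.
#' @param p_ref Reference pressure, hPa.
#' @return Virtual potential temperature, K.
#' @export
virtual_potential_temperature <- function(tv_k, pressure_hpa, p_ref = 1000) {
  tv_k * (p_ref / pressure_hpa)^KAPPA
}

#' Integrated Businger-Dyer stability corrections
#'
#' Flux-profile correction functions for momentum (`psi_m`) and heat
#' (`psi_h`) as functions of the stability parameter `zeta = z/L`, in the
#' Businger-Dyer form with Paulson's unstable integration: for `zeta < 0`,
#' `x = (1 - 16 zeta)^(1/4)`,
#' `psi_m = 2 ln((1+x)/2) + ln((1+x^2)/2) - 2 atan(x) + pi/2` and
#' `psi_h = 2 ln((1+x^2)/2)`; for `zeta >= 0` both equal `-5 zeta`.
#'
#' @param zeta Stability parameter z/L (dimensionless), any finite value.
#' @return Correction value(s), dimensionless; 0 at neutral (`zeta = 0`).
#' @export
#' @examples
#' psi_m(0)      # 0: neutral
#' psi_m(-1)     # positive: unstable enhancement
#' psi_h(0.5)    # -2.5: stable suppression
psi_m <- function(zeta) {
  out <- -5 * zeta
  un <- !is.na(zeta) & zeta < 0
  if (any(un)) {
    x <- (1 - 16 * zeta[un])^0.25
    out[un] <- 2 * log((1 + x) / 2) + log((1 + x^2) / 2) -
      2 * atan(x) + pi / 2
  }
  out
}

#' @rdname psi_m
#' @export
psi_h <- function(zeta) {
  out <- -5 * zeta
  un <- !is.na(zeta) & zeta < 0
  if (any(un)) {
    x <- (1 - 16 * zeta[un])^0.25
    out[un] <- 2 * log((1 + x^2) / 2)
  }
  out
}

# Thermodynamic state at the two temperature heights for one sample.
# Pressure at each height comes from the hydrostatic adjustment with the
# two-level mean temperature; virtual (potential) temperature applies the
# humidity correction with the near-surface RH at both levels.
thermo_state <- function(t1_c, t2_c, rh, p_sfc, z_t, const) {
  t_mean_k <- (t1_c + t2_c) / 2 + 273.15
  p1 <- pressure_at_height(p_sfc, z_t[1], t_mean_k, const$g)
  p2 <- pressure_at_height(p_sfc, z_t[2], t_mean_k, const$g)
  tv1 <- virtual_temperature(t1_c, rh, p1)
  tv2 <- virtual_temperature(t2_c, rh, p2)
  list(
    tv1 = tv1, tv2 = tv2, p1 = p1, p2 = p2,
    thv1 = virtual_potential_temperature(tv1, p1, const$p_ref),
    thv2 = virtual_potential_temperature(tv2, p2, const$p_ref)
  )
}

# One-sample fixed-point Obukhov iteration. Returns a list of scalars.
solve_obukhov_one <- function(U, t1_c, t2_c, rh, p_sfc, z_u, z_t, const,
                              tol, max_iter, u_min, neutral_inv_l,
                              dthv_neutral, zeta_max) {
  k <- const$k
  g <- const$g
  z0 <- const$z0
  na_res <- list(L = NA_real_, u_star = NA_real_, theta_star = NA_real_,
                 zeta = NA_real_, converged = FALSE, n_iter = 0L)

  if (anyNA(c(U, t1_c, t2_c, rh, p_sfc))) {
    return(c(na_res, status = "missing"))
  }
  if (U < u_min) {
    return(c(na_res, status = "calm"))
  }

  th <- thermo_state(t1_c, t2_c, rh, p_sfc, z_t, const)
  dthv <- th$thv2 - th$thv1
  tv_mean <- (th$tv1 + th$tv2) / 2
  log_u <- log(z_u / z0)
  log_t <- log(z_t[2] / z_t[1])
  u_star_neutral <- k * U / log_u

  if (abs(dthv) < dthv_neutral) {
    return(list(L = Inf, u_star = u_star_neutral, theta_star = 0,
                zeta = 0, converged = TRUE, n_iter = 0L, status = "neutral"))
  }

  inv_l <- 0          # start from neutral (psi terms vanish)
  d_prev <- 0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    u_star <- k * U /
      (log_u - psi_m(z_u * inv_l) + psi_m(z0 * inv_l))
    theta_star <- k * dthv /
      (log_t - psi_h(z_t[2] * inv_l) + psi_h(z_t[1] * inv_l))
    if (!is.finite(u_star) || u_star <= 0) {
      return(c(na_res[c("L", "u_star", "theta_star", "zeta")],
               converged = FALSE, n_iter = iter, status = "failed"))
    }
    l_new <- tv_mean * u_star^2 / (k * g * theta_star)
    inv_new <- 1 / l_new
    d <- inv_new - inv_l
    # damp 1/L updates when successive steps flip sign (oscillation)
    if (iter > 1L && d * d_prev < 0) {
      inv_new <- inv_l + 0.5 * d
      d <- inv_new - inv_l
    }
    d_prev <- d
    if (abs(inv_new) < neutral_inv_l) {
      return(list(L = Inf, u_star = u_star_neutral, theta_star = 0,
                  zeta = 0, converged = TRUE, n_iter = iter,
                  status = "neutral"))
    }
    rel <- abs(d) / abs(inv_new)   # equals |delta L / L| to first order
    inv_l <- inv_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }

  L <- 1 / inv_l
  zeta <- z_u * inv_l
  u_star <- k * U / (log_u - psi_m(z_u * inv_l) + psi_m(z0 * inv_l))
  theta_star <- k * dthv /
    (log_t - psi_h(z_t[2] * inv_l) + psi_h(z_t[1] * inv_l))
  status <- if (!converged) {
    "no_converge"
  } else if (zeta > zeta_max) {
    "very_stable"   # outside similarity validity; values kept but flagged
  } else {
    "ok"
  }
  list(L = L, u_star = u_star, theta_star = theta_star, zeta = zeta,
       converged = converged, n_iter = iter, status = status)
}

#' Hourly Obukhov length from two-level tower data
#'
#' Iteratively solves the Monin-Obukhov flux-profile relations for the
#' Obukhov length `L`, friction velocity `u*` and temperature scale
#' `theta*`, hour by hour, from a single-height wind speed and a two-level
#' temperature difference:
#'
#' * `L = (Tv1 + Tv2)/2 * u*^2 / (k g theta*)`
#' * `u* = k U(z_u) / [ln(z_u/z0) - psi_m(z_u/L) + psi_m(z0/L)]`
#' * `theta* = k (thv2 - thv1) / [ln(z2/z1) - psi_h(z2/L) + psi_h(z1/L)]`
#'
#' with the Businger-Dyer corrections [psi_m()]/[psi_h()]. Virtual
#' (potential) temperatures apply the humidity correction from near-surface
#' relative humidity, and pressure at each height follows the hydrostatic
#' adjustment of the surface pressure. The fixed-point iteration starts
#' from neutral and damps oscillating `1/L` updates by half; `L > 0` is
#' stable, `L < 0` unstable, and hours with `|1/L|` below `neutral_inv_l`
#' (or a virtual-potential-temperature difference under `dthv_neutral`)
#' return the neutral sentinel `L = Inf` with the log-law friction velocity.
#'
#' @param data Data frame with one row per hour. Required columns: `U`
#'   (wind speed at `z_u`, m s^-1), `T1` and `T2` (air temperature at the
#'   lower and upper temperature heights, degC), `RH` (near-surface
#'   relative humidity, percent). Optional: `p_sfc` (surface pressure,
#'   hPa; a constant 1010 hPa is assumed with a warning when absent) and
#'   `timestamp`, carried through to the output.
#' @param z_u Wind measurement height, m (50 or 100 on a 100-m mast).
#' @param z_t Lengths-2 vector of temperature measurement heights, m.
#' @param const [met_constants()].
#' @param tol Relative convergence tolerance on `L`.
#' @param max_iter Maximum fixed-point iterations per hour.
#' @param u_min Calm-wind threshold, m s^-1; below it the hour gets
#'   status `"calm"` and no result.
#' @param neutral_inv_l Neutrality threshold on `|1/L|`, m^-1.
#' @param dthv_neutral Neutrality threshold on `|thv2 - thv1|`, K.
#' @param zeta_max Stable-branch validity cap on `zeta = z_u/L`; beyond it
#'   the hour is flagged `"very_stable"` rather than extrapolated.
#' @return A tibble with one row per input row: `L` (m), `u_star` (m s^-1),
#'   `theta_star` (K), `zeta`, `converged`, `n_iter`, `status` (one of
#'   `"ok"`, `"neutral"`, `"calm"`, `"very_stable"`, `"no_converge"`,
#'   `"missing"`, `"failed"`), plus `timestamp` if supplied. The input
#'   `z_u` is recorded in the `z_u` attribute.
#' @export
#' @examples
#' solve_obukhov(data.frame(U = 3, T1 = 26, T2 = 25.6, RH = 60,
#'                          p_sfc = 1010), z_u = 50)
solve_obukhov <- function(data, z_u, z_t = c(2, 50), const = met_constants(),
                          tol = 1e-4, max_iter = 50L, u_min = 0.1,
                          neutral_inv_l = 1e-6, dthv_neutral = 1e-3,
                          zeta_max = 5) {
  stopifnot(is.data.frame(data), length(z_t) == 2, z_t[1] < z_t[2],
            const$z0 < z_u, tol > 0, max_iter >= 1)
  need <- c("U", "T1", "T2", "RH")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "))
  }
  if (!"p_sfc" %in% names(data)) {
    rlang::warn("no `p_sfc` column; assuming constant 1010 hPa surface pressure")
    data$p_sfc <- 1010
  }
  res <- purrr::pmap(
    list(data$U, data$T1, data$T2, data$RH, data$p_sfc),
    function(U, t1, t2, rh, p) {
      solve_obukhov_one(U, t1, t2, rh, p, z_u, z_t, const, tol, max_iter,
                        u_min, neutral_inv_l, dthv_neutral, zeta_max)
    }
  )
  out <- dplyr::bind_rows(lapply(res, tibble::as_tibble))
  if ("timestamp" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(timestamp = data$timestamp), out)
  }
  attr(out, "z_u") <- z_u
  out
}

#' Combine Obukhov-length series from two wind heights
#'
#' When wind is measured at two heights, `L` can be estimated independently
#' from each. This reports the Pearson correlation between the two hourly
#' series over hours where both converged non-neutrally, and combines them
#' as the per-hour mean of the two `L` values (neutral sentinels and failed
#' hours excluded from averaging; an hour with only one usable value keeps
#' that value).
#'
#' @param res_a,res_b Results from [solve_obukhov()] at the two heights,
#'   row-aligned (same hours in the same order).
#' @return An object of class `dual_obukhov`: a list with `series` (tibble
#'   with `L_a`, `L_b`, `L` combined, `status`), `correlation`, and
#'   `n_pairs`. [generics::tidy()] returns the series,
#'   [generics::glance()] the correlation summary.
#' @export
combine_dual_heights <- function(res_a, res_b) {
  stopifnot(nrow(res_a) == nrow(res_b))
  usable <- function(r) r$status %in% c("ok", "very_stable") & is.finite(r$L)
  ua <- usable(res_a)
  ub <- usable(res_b)
  both <- ua & ub
  n_pairs <- sum(both)
  correlation <- if (n_pairs >= 2) {
    stats::cor(res_a$L[both], res_b$L[both])
  } else {
    rlang::warn("fewer than 2 paired converged hours; correlation undefined")
    NA_real_
  }
  la <- ifelse(ua, res_a$L, NA_real_)
  lb <- ifelse(ub, res_b$L, NA_real_)
  combined <- dplyr::case_when(
    both ~ (la + lb) / 2,
    ua ~ la,
    ub ~ lb,
    res_a$status == "neutral" | res_b$status == "neutral" ~ Inf,
    .default = NA_real_
  )
  status <- dplyr::case_when(
    both ~ "both",
    ua | ub ~ "single",
    is.infinite(combined) ~ "neutral",
    .default = "none"
  )
  series <- tibble::tibble(L_a = la, L_b = lb, L = combined, status = status)
  if ("timestamp" %in% names(res_a)) {
    series <- dplyr::bind_cols(
      tibble::tibble(timestamp = res_a$timestamp), series)
  }
  structure(list(series = series, correlation = correlation,
                 n_pairs = n_pairs),
            class = "dual_obukhov")
}

#' @export
print.dual_obukhov <- function(x, ...) {
  cat("Dual-height Obukhov combination\n")
  cat(sprintf("  paired converged hours: %d\n", x$n_pairs))
  cat(sprintf("  Pearson correlation:    %s\n",
              formatC(x$correlation, digits = 4, format = "fg")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.dual_obukhov <- function(x, ...) x$series

#' @exportS3Method generics::glance
glance.dual_obukhov <- function(x, ...) {
  tibble::tibble(correlation = x$correlation, n_pairs = x$n_pairs)
}

#' Daily daytime stability summary
#'
#' Fraction of daytime hours that are dynamically unstable (`L < 0`),
#' stable (`L > 0`) or neutral, per day, counting only hours with a usable
#' stability estimate. Non-converged, calm and missing hours are excluded
#' from the denominator.
#'
#' @param results [solve_obukhov()] output containing a `timestamp` column,
#'   or the `series` of a [combine_dual_heights()] object (columns
#'   `timestamp`, `L`).
#' @param hours Daytime hour labels (1-24 local time, hour `h` covering
#'   `(h-1, h]`) to summarise.
#' @return Tibble with `date`, `n_hours` (usable daytime hours),
#'   `frac_unstable`, `frac_stable`, `frac_neutral`.
#' @export
daytime_stability_summary <- function(results, hours = 10:16) {
  stopifnot("timestamp" %in% names(results), "L" %in% names(results))
  lab <- hour_label(results$timestamp)
  df <- tibble::tibble(
    date = lab$date, hour = lab$hour, L = results$L,
    usable = if ("status" %in% names(results)) {
      results$status %in% c("ok", "very_stable", "neutral", "both", "single")
    } else {
      !is.na(results$L)
    }
  )
  df |>
    dplyr::filter(.data$hour %in% hours, .data$usable, !is.na(.data$L)) |>
    dplyr::group_by(date = .data$date) |>
    dplyr::summarise(
      n_hours = dplyr::n(),
      frac_unstable = mean(.data$L < 0),
      frac_stable = mean(is.finite(.data$L) & .data$L > 0),
      frac_neutral = mean(is.infinite(.data$L)),
      .groups = "drop"
    )
}
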