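test_that("virtual temperature reduces to dry air and adds moisture warmth", {
  expect_equal(virtual_temperature(25, 0, 1010), 298.15)
  # saturated warm air: verify against a hand evaluation of the formulas
  t <- 30; p <- 1013.25
  es <- 6.112 * exp(17.67 * t / (t + 243.5))
  q <- 0.622 * es / (p - 0.378 * es)
  expect_equal(virtual_temperature(t, 100, p),
               (t + 273.15) * (1 + 0.608 * q), tolerance = 1e-12)
  # moist air is always virtually warmer
  set.seed(5)
  tt <- runif(50, -5, 40); rh <- runif(50, 0, 100)
  expect_true(all(virtual_temperature(tt, rh, 1000) >= tt + 273.15))
  # vapour pressure exceeding total pressure is non-physical
  expect_error(virtual_temperature(45, 100, 50), "non-physical")
})

test_that("hydrostatic pressure adjustment is exact and monotone", {
  expect_equal(pressure_at_height(1013, 0, 290), 1013)
  expect_equal(pressure_at_height(1000, 50, 290),
               1000 * exp(-9.81 * 50 / (287.05 * 290)), tolerance = 1e-12)
  z <- seq(0, 4000, by = 100)
  expect_true(all(diff(pressure_at_height(1010, z, 285)) < 0))
})

test_that("Businger-Dyer corrections match their closed forms", {
  expect_equal(psi_m(0), 0)
  expect_equal(psi_h(0), 0)
  expect_equal(psi_m(0.1), -0.5)
  expect_equal(psi_h(0.3), -1.5)
  # unstable branch vs numerical quadrature of (1 - phi_m(x))/x,
  # phi_m = (1 - 16 zeta)^(-1/4)
  quad <- integrate(function(x) (1 - (1 - 16 * x)^(-0.25)) / x,
                    lower = -1, upper = -1e-12,
                    rel.tol = 1e-10, subdivisions = 2000L)
  expect_equal(psi_m(-1), -quad$value, tolerance = 1e-6)
  quad_h <- integrate(function(x) (1 - (1 - 16 * x)^(-0.5)) / x,
                      lower = -1, upper = -1e-12,
                      rel.tol = 1e-10, subdivisions = 2000L)
  expect_equal(psi_h(-1), -quad_h$value, tolerance = 1e-6)
})

test_that("neutral stratification yields the log-law friction velocity", {
  s <- sample_with_dthv(U = 5, dthv = 0)
  r <- solve_obukhov(s, z_u = 50)
  expect_equal(r$status, "neutral")
  expect_true(is.infinite(r$L))
  expect_equal(r$u_star, 0.4 * 5 / log(50 / 0.25), tolerance = 1e-12)
  expect_equal(r$theta_star, 0)
})

test_that("solver matches the residual-scan oracle on canonical cases", {
  # subcritical stable case
  st <- sample_with_dthv(U = 3, dthv = 0.5)
  r_st <- solve_obukhov(st, z_u = 50)
  o_st <- oracle_obukhov(3, 0.5, tv_mean_of(st))
  expect_equal(r_st$status, "ok")
  expect_gt(r_st$L, 0)
  expect_true(o_st$found)
  expect_lt(abs(r_st$L - o_st$L) / abs(o_st$L), 0.01)

  # unstable case: negative L, matches oracle
  un <- sample_with_dthv(U = 3, dthv = -1.0, t1_c = 27)
  r_un <- solve_obukhov(un, z_u = 50)
  o_un <- oracle_obukhov(3, -1.0, tv_mean_of(un))
  expect_lt(r_un$L, 0)
  expect_true(o_un$found)
  expect_lt(abs(r_un$L - o_un$L) / abs(o_un$L), 0.01)
})

test_that("a supercritical stable sample has no similarity solution", {
  # weak wind + strong two-level warming: bulk Richardson beyond critical;
  # the fixed-point map has no root and the solver must not pretend it does
  sup <- sample_with_dthv(U = 2, dthv = 0.5)
  r <- solve_obukhov(sup, z_u = 50)
  expect_false(r$converged)
  expect_equal(r$status, "no_converge")
  expect_false(oracle_obukhov(2, 0.5, tv_mean_of(sup))$found)
})

test_that("converged L sign always follows the stratification sign", {
  set.seed(7)
  n_checked <- 0
  for (i in 1:60) {
    dthv <- runif(1, -2, 2)
    s <- sample_with_dthv(U = runif(1, 0.5, 10), dthv = dthv)
    r <- solve_obukhov(s, z_u = 50)
    if (r$status %in% c("ok", "very_stable")) {
      n_checked <- n_checked + 1
      expect_equal(sign(r$L), sign(dthv))
      expect_equal(sign(r$theta_star), sign(r$L))
      expect_gt(r$u_star, 0)
    }
  }
  expect_gt(n_checked, 20)
})

test_that("calm and missing hours are flagged, not solved", {
  r <- solve_obukhov(
    tibble::tibble(U = c(0.05, NA), T1 = c(25, 25), T2 = c(24, 24),
                   RH = c(50, 50), p_sfc = c(1010, 1010)), z_u = 50)
  expect_equal(r$status, c("calm", "missing"))
  expect_true(all(is.na(r$L)))
})

test_that("a missing pressure column falls back to 1010 hPa with a warning", {
  expect_warning(
    r <- solve_obukhov(tibble::tibble(U = 3, T1 = 26, T2 = 25, RH = 50),
                       z_u = 50),
    "1010")
  expect_lt(r$L, 0)
})

test_that("halving the tolerance barely moves converged L", {
  set.seed(17)
  for (i in 1:40) {
    s <- sample_with_dthv(U = runif(1, 0.5, 10), dthv = runif(1, -2, 2))
    r1 <- solve_obukhov(s, z_u = 50, tol = 1e-4)
    r2 <- solve_obukhov(s, z_u = 50, tol = 5e-5)
    expect_lte(r1$n_iter, 50)
    if (r1$status == "ok" && r2$status == "ok") {
      expect_lt(abs(r1$L - r2$L) / abs(r2$L), 0.005)
    }
  }
})

test_that("dual-height combination averages and correlates as specified", {
  set.seed(19)
  ts <- hazemet:::hourly_stamps(as.Date("2017-12-13"), 1)
  base <- tibble::tibble(
    timestamp = ts, L = rnorm(24, 100, 30), u_star = 0.3,
    theta_star = 0.05, zeta = 0.5, converged = TRUE, n_iter = 5L,
    status = "ok")
  # identical series
  d <- combine_dual_heights(base, base)
  expect_equal(d$correlation, 1)
  expect_equal(d$series$L, base$L)
  # exact linear relation: combined is the midpoint series
  twice <- dplyr::mutate(base, L = 2 * L)
  d2 <- combine_dual_heights(base, twice)
  expect_equal(d2$correlation, 1)
  expect_equal(d2$series$L, 1.5 * base$L)
  # one series unusable: combined equals the other, correlation undefined
  dead <- dplyr::mutate(base, L = NA_real_, status = "calm")
  expect_warning(d3 <- combine_dual_heights(base, dead), "undefined")
  expect_equal(d3$series$L, base$L)
  expect_true(is.na(d3$correlation))
  # broom-style accessors
  expect_s3_class(tidy(d2), "tbl_df")
  expect_equal(glance(d2)$n_pairs, 24L)
})

test_that("daytime stability summary counts unstable fractions per day", {
  ts <- hazemet:::hourly_stamps(as.Date("2017-12-13"), 2)
  L <- rep(100, 48)
  hours <- rep(1:24, 2)
  L[hours %in% 10:16] <- -50          # all daytime hours unstable
  res <- tibble::tibble(timestamp = ts, L = L, status = "ok")
  s <- daytime_stability_summary(res)
  expect_equal(nrow(s), 2)
  expect_equal(s$frac_unstable, c(1, 1))
  expect_equal(s$n_hours, c(7L, 7L))
})
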