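---
title: "Methods: haze-episode meteorology with hazemet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haze-episode meteorology with hazemet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazemet)
library(dplyr)
```

`hazemet` quantifies how local meteorology couples to urban particulate
haze: it screens and aggregates hourly observations, segments haze events
from daily PM2.5, estimates near-surface dynamic stability from tower
profiles, detects temperature inversions in morning soundings, and grids
fire hotspots by episode phase. This vignette is the package's account of
the science behind each stage, the parameters that matter, and the design
choices made where the method leaves room.

## Quality control and daily statistics

Hourly values are screened against closed physical intervals
(`qc_ranges()`): PM 3–1000 µg m⁻³ (the 3 µg m⁻³ floor is the monitor's
detection limit, so a reading of 2 is flagged, not kept as a small value),
temperature −5–50 °C, relative humidity 0–100 %, wind speed 0–50 m s⁻¹,
wind direction 0–360°, rain 0–1000 mm h⁻¹, global radiation 0–1000 W m⁻².
Out-of-range values are *flagged*, never dropped, so the record of what
the instrument reported survives. There is no automated outlier detection;
erratic values a human spots are supplied as an explicit exclusion list,
which keeps the screening reproducible.

Daily statistics use the 1–24 LT hour-label convention — hour *h* covers
(*h*−1, *h*], so a stamp at midnight is hour 24 of the previous day — and
require at least half of the window's hours to be valid, *inclusively*:
12 usable hours of 24 yield a mean, 11 yield a missing day. Global
radiation is averaged over 11–16 LT only, representing late-morning to
mid-afternoon insolation rather than diluting it with zero night hours.
Wind direction is averaged as the direction of the mean unit vector
(an open choice: arithmetic means of angles near north are meaningless,
and nothing in the daily products depends on speed-weighting).

The daily PM2.5/PM10 ratio is the 24-h mean of *hourly* ratios over hours
where both fractions are valid and PM10 is positive — not the ratio of
daily means. The two differ whenever the coarse fraction varies across
the day, and the mean-of-ratios form weights each hour's aerosol
composition equally.

Gap-filling regresses the target on a reference station over paired valid
hours (ordinary least squares, minimum 100 pairs) and predicts only the
missing hours; originally valid hours are never altered, and filled hours
carry a distinct flag so downstream validity counts can include or audit
them.

## Haze days, events, and episode phases

A haze day has daily PM2.5 at or above 50 µg m⁻³ — the Thai daily ambient
standard, threshold inclusive — at one station or more; requiring only one
station makes the calendar robust to single-station outages. A haze event
is a maximal run of consecutive haze days. Days where every station is
missing are *indeterminate*: by default they break a run (conservative),
but `segment_events(bridge_missing = TRUE)` carries a single indeterminate
day flanked by haze days, which is how a monitoring gap inside an
obviously continuous event is usually read. Pre- and post-event windows
are plain calendar labels attached to an event (e.g. 7 days before, 4
after); they make no claim of being haze-free beyond the event's own
maximality.

## Obukhov length from a two-level tower profile

Near-surface dynamic stability is summarised by the Obukhov length *L*,
via Monin–Obukhov similarity applied to one wind height `z_u` (50 or
100 m) and two temperature heights (2 and 50 m):

$$L = \frac{\tfrac12 (T_{v1}+T_{v2})\,u_*^2}{k\,g\,\theta_*},\qquad
u_* = \frac{k\,U(z_u)}{\ln(z_u/z_0) - \Psi_M(z_u/L) + \Psi_M(z_0/L)},\qquad
\theta_* = \frac{k\,(\theta_{v2}-\theta_{v1})}{\ln(z_2/z_1) -
\Psi_H(z_2/L) + \Psi_H(z_1/L)}.$$

Humidity enters through virtual temperature
($T_v = T(1 + 0.608q)$, with $q$ from relative humidity via the Bolton
saturation vapour pressure), pressure at each height through the
hydrostatic adjustment of surface pressure, and potential temperature
through the Poisson relation with exponent 0.2854. When no surface
pressure is supplied a constant 1010 hPa is assumed with a warning —
adequate because *L* depends on pressure only through weak density and
Poisson factors.

Assumptions worth keeping in mind: a horizontally homogeneous surface
layer with constant fluxes between 2 and 50 m, a single roughness length
(`z0 = 0.25` m, the Davenport "rough" class for sparsely built suburban
terrain with paddy fields), and no displacement height.

### Numerical choices

* **Stability functions.** Businger–Dyer with constants (16, 5):
  unstable $\Psi$ from Paulson's integrated forms with
  $x = (1-16\zeta)^{1/4}$, stable $\Psi_M = \Psi_H = -5\zeta$. These are
  the most widely used constants; the formulation does not pin them down
  more finely than observational scatter does.
* **Iteration.** Fixed-point from the neutral start ($\Psi \equiv 0$),
  updating $1/L$ and damping the update by half whenever successive steps
  flip sign. A Newton scheme converges faster when it converges, but the
  damped fixed point is robust on the stable branch where the linear
  $-5\zeta$ correction overshoots. Convergence is declared at a relative
  change in *L* below `tol = 1e-4` (~50 iterations maximum; typical hours
  converge in 5–10). Halving the tolerance moves converged *L* by well
  under 0.5 %, which the test suite checks on randomised samples.
* **Neutral sentinels.** Hours with $|\theta_{v2}-\theta_{v1}| <
  0.001$ K (below any thermometer pair's resolution) or $|1/L| <
  10^{-6}\,\mathrm{m^{-1}}$ short-circuit to the neutral result
  $L=\infty$, $u_* = kU/\ln(z_u/z_0)$, avoiding division noise near
  neutrality.
* **Degenerate inputs.** Wind below 0.1 m s⁻¹ (cup-anemometer threshold)
  is "calm" — no result rather than a wild one. Converged hours with
  $\zeta = z_u/L > 5$ are flagged `very_stable`: the flux-profile
  relations are extrapolations there.
* **No solution exists** for some strongly stable hours: when the bulk
  Richardson number of the two-level sample exceeds the critical value
  implied by the (16, 5) constants, the fixed-point map $1/L \mapsto
  1/L_{\mathrm{implied}}$ has no root and the iteration diverges toward
  $L \to 0$. Such hours are flagged `no_converge` and excluded from daily
  statistics — this is a physical statement (turbulence collapse is
  outside similarity theory), not a solver deficiency. The test suite
  verifies against an independent residual-scan oracle both that
  converged hours match the true root to 1 % and that flagged hours
  genuinely have no in-range root.

When wind is available at two heights, *L* is estimated from each
separately; the package reports their Pearson correlation over paired
converged hours and uses the per-hour mean as the combined series
(neutral sentinels excluded from averaging — the mean of 100 m and
$\infty$ is not meaningful). The daytime summary reports the fraction of
10–16 LT hours that are unstable, the quantity most relevant to afternoon
pollutant dilution.

## Temperature inversions in soundings

Within a sounding truncated at 4 km, an inversion layer is a *maximal*
run of successive levels with strictly increasing temperature; the layer
spans the run's endpoints and its intensity is
$IV = (T_{top}-T_{bottom})/(z_{top}-z_{bottom}) \times 100$ °C per
100 m. "Monotonically increasing" is read strictly: an isothermal level
terminates a run, which costs nothing because an isothermal layer has
$IV = 0$ and would be filtered anyway. Filtering keeps layers with
$IV > 0.1$ (strict, so 0.10 exactly is dropped) and bottom at or above
100 m — shallower inversions are routine radiative surface cooling at a
07 LT release, not episode meteorology. Banding is by the layer *bottom*:
[100, 1500) m is "low" (inside a conservatively thick boundary layer,
where an inversion caps dilution), [1500, 4000) "upper" (typically
subsidence aloft); a layer straddling 1500 m is not split, because the
physical object is one warming layer. The IV threshold applies uniformly
to both bands. Heights are above ground; for coastal stations a few
metres above sea level the MSL/AGL distinction is within instrument
noise, but the reader subtracts station elevation for generality.

The per-episode summary counts, per phase: sounding days with at least
one low layer, days with multiple low layers (failed inversion breakup
leaves stacked layers), the min/max/mean low-band IV, days with upper
layers, and days with no sounding — reported separately rather than
silently treated as inversion-free.

## Fire hotspots

Active-fire points are binned per episode phase onto a grid (default
0.5°) with edges anchored at integer multiples of the cell size and
half-open membership [edge, edge + cell), so every point lands in exactly
one cell and grid totals conserve point counts exactly — the property the
tests check against a per-point loop. The anchor choice is arbitrary in
principle; multiples-of-cell-size edges make cells line up with the map
graticule. No confidence filtering is applied by default.

## The synthetic generators

Because hourly monitoring and tower records of the kind this pipeline
consumes are typically available on request only, the package ships
seeded generators that emulate their statistical structure. The episode
scenario defaults describe a December cold-surge episode: 6 pre-event
days, an 8-day haze event, 5 post-event days; the surge arriving on
episode day 5 drops the daily-mean temperature by 9.5 °C and relative
humidity by 29 points within a day, multiplies wind by 2.5 while active,
and relaxes with a 4-day e-folding time; daily PM2.5 is 35 µg m⁻³
outside the event and elevated by 30 during it, with a ±40 % diurnal
factor peaking at night/early morning; the PM2.5/PM10 ratio is 0.8,
characteristic of haze dominated by combustion rather than coarse dust;
pre-surge days are cloudier (half radiation). The 2 m–50 m temperature
contrast oscillates ±1.5 °C day/night — deliberately larger than the
~0.47 °C adiabatic increment across 48 m, so afternoons are genuinely
superadiabatic (unstable) and nights genuinely stable, exercising both
solver branches. Noise is Gaussian and independent across hours, and
missing data are injected as block outages of consecutive hours, the
realistic failure mode for a station and the one that stresses the
50 %-valid rule.

What the generators do *not* emulate: temporal autocorrelation of noise,
spatially correlated multi-station fields beyond a shared regional
signal, wet scavenging by rain, aerosol–radiation feedback on the
temperature profile, and real synoptic variability. Passing tests
therefore demonstrate that the pipeline's logic and numerics are correct
under the assumed structure — not that the structure exhausts real data.

Two generators are exact inverses of analysis stages and serve as test
oracles. `gen_sounding()` builds piecewise-linear profiles whose implanted
warming layers detection must recover with exact bounds and intensities
(to 10⁻⁹ °C/100 m). `gen_most_consistent_sample()` inverts the
flux-profile relations: fixing the true *L*, it derives $u_*$, $\theta_*$
and the implied two-level temperatures, and the solver must recover *L*
within 2 % (observed: within ~0.01 %); the residual tolerance exists
because the generator's internal fixed point (temperatures depend on
pressures depend on temperatures) is finite-precision, not because the
equations differ.

## Problem sizes

The test suite runs entirely on generated data: 200 random samples for
the solver-vs-oracle comparison, 1000 random calendars for segmentation,
100 random sounding scenarios for the inversion round-trip, 10,000 random
points for grid conservation, and 19-day episodes (456 hours) for the
pipeline checks — sizes at which every oracle (dense residual scan,
day-by-day scan, per-point loop) is itself fast and trustworthy.
`scripts/acceptance.R` recomputes the headline quantities on the same
scales from a single command-line seed.

## Known limitations

* The stability module assumes constant-flux similarity between 2 and
  50 m; during deep stable nights or transitions the 50 m level can sit
  above the surface layer, and flagged (`very_stable`, `no_converge`)
  hours should be interpreted as "outside the theory", not discarded
  silently — they are reported with status codes for exactly that reason.
* Daily wind-direction averaging is unweighted by speed; calm-dominated
  days can have poorly defined mean directions.
* The haze-day rule is single-pollutant and threshold-based; no AQI or
  multi-pollutant logic is provided.
* Back-trajectory modelling and synoptic-chart classification are out of
  scope; the fire-gridding module provides the transport-side context
  that can be computed from point data alone.
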