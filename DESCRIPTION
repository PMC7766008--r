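Package: hazemet
Title: Meteorological Analysis of Urban Haze Episodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing the local meteorology of
    urban particulate-haze episodes. Quality-screens and aggregates hourly
    air-quality and tower observations to daily values, segments haze events
    from daily PM2.5 exceedances, estimates hourly Obukhov length and friction
    velocity from two-level tower profiles by iterating the Monin-Obukhov
    flux-profile relations with Businger-Dyer stability corrections, detects
    and scores temperature-inversion layers in radiosonde soundings, and grids
    satellite active-fire hotspots by episode period. A seeded synthetic-data
    generator emulates cold-surge episode structure (abrupt temperature and
    humidity drops, wind peaks, night/morning PM2.5 diurnality, implanted
    inversion layers) so the full pipeline is testable without restricted
    station data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
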