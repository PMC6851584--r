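Package: wintertrends
Title: Winter Climate-Change Indicators and Nonparametric Trend Analysis for
    Daily Station Weather
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for computing threshold-based winter climate-change
    indicators (frost, ice, thaw, extreme-cold, snowmaking, snow-cover,
    rain-on-snow and related days) from daily station weather records, and for
    testing their long-term trends with Mann-Kendall, Sen slope and regional
    (site-blocked) Kendall statistics. Includes reading and validation of
    GHCN-Daily-like station files, completeness screening and snow gap-filling,
    a degree-day snow-water-equivalent model with grid calibration, and a
    seeded synthetic daily-weather generator so the full pipeline can be
    exercised and validated against known ground truth without any data
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
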