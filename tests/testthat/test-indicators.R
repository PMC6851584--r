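test_that("dates map to winters labeled by ending year", {
  expect_equal(assign_winter(as.Date("2000-11-01")), 2001L)
  expect_equal(assign_winter(as.Date("2000-12-31")), 2001L)
  expect_equal(assign_winter(as.Date("2001-01-01")), 2001L)
  expect_equal(assign_winter(as.Date("2001-05-31")), 2001L)
  expect_true(is.na(assign_winter(as.Date("2001-06-15"))))
  expect_true(is.na(assign_winter(as.Date("2001-10-31"))))
  # leap winters are one day longer; Feb 29 is an ordinary winter day
  expect_equal(winter_length(2001), 212L)
  expect_equal(winter_length(2004), 213L)
  expect_equal(assign_winter(as.Date("2004-02-29")), 2004L)
})

test_that("day classification matches a truth-table oracle across threshold boundaries", {
  grid <- expand.grid(
    tmax = c(-30.1, -30, -18.1, -18, -5.1, -5, -0.1, 0, 0.1, 5, NA),
    tmin = c(-35, -30.1, -30, -18.1, -18, -5.1, -5, -0.1, 0, 0.1, NA),
    swe = c(0, 0.1, 25, NA),
    rain = c(0, 0.1, 5, NA)
  )
  grid <- grid[is.na(grid$tmax) | is.na(grid$tmin) | grid$tmin <= grid$tmax, ]
  got <- classify_day(tmax = grid$tmax, tmin = grid$tmin, swe = grid$swe,
                      rain = grid$rain)
  bad <- character(0)
  for (i in seq_len(nrow(grid))) {
    want <- bf_classify_day(grid$tmax[i], grid$tmin[i], grid$swe[i], grid$rain[i])
    for (flag in names(want)) {
      if (!identical(got[[flag]][i], want[[flag]])) {
        bad <- c(bad, sprintf("%s at tmax=%s tmin=%s swe=%s rain=%s",
                              flag, grid$tmax[i], grid$tmin[i],
                              grid$swe[i], grid$rain[i]))
      }
    }
  }
  expect_identical(bad, character(0))
})

test_that("specific classification cases behave as defined", {
  d1 <- classify_day(tmax = -2, tmin = -6, swe = 10, rain = 0)
  expect_true(d1$ice && d1$frost && d1$snowmaking && d1$snow_covered)
  expect_false(d1$thaw || d1$bare_ground || d1$rain_on_snow || d1$mud)

  d2 <- classify_day(tmax = 5, tmin = -1, swe = 0, rain = 0)
  expect_true(d2$thaw && d2$frost && d2$bare_ground && d2$mud)
  expect_false(d2$ice || d2$snow_covered || d2$frozen_ground)

  # boundary: tmax exactly 0 is neither thaw nor ice
  d3 <- classify_day(tmax = 0, tmin = -3, swe = 0, rain = 0)
  expect_false(d3$thaw || d3$ice || d3$frozen_ground || d3$mud)
  expect_true(d3$frost)

  d4 <- classify_day(tmax = 2, tmin = 0, swe = 20, rain = 5)
  expect_true(d4$rain_on_snow)
})

uniform_winter_days <- function(winter = 2001, tmax = -5, tmin = -10,
                                swe = 10, rain = 0) {
  dates <- wintertrends:::winter_window(winter)
  flags <- classify_day(tmax = tmax, tmin = tmin, swe = rep(swe, length(dates)),
                        rain = rep(rain, length(dates)))
  flags$date <- dates
  flags
}

test_that("winter counting sums flags, applies snowmaking windows, and reports missing as NA", {
  cw <- count_winter_indicators(uniform_winter_days(), 2001)
  expect_equal(cw$ice, 212L)
  expect_equal(cw$frost, 212L)
  expect_equal(cw$snowmaking, 212L)
  expect_equal(cw$snow_covered, 212L)
  expect_equal(cw$thaw, 0L)
  expect_equal(cw$mud, 0L)
  expect_equal(cw$den_tmin, 212L)

  # snowmaking-capable days only on 24 and 26 Dec -> early window counts 1
  days <- uniform_winter_days(tmin = -1)         # never cold enough
  cold <- days$date %in% as.Date(c("2000-12-24", "2000-12-26"))
  days$snowmaking[cold] <- TRUE
  cw2 <- count_winter_indicators(days, 2001)
  expect_equal(cw2$snowmaking_before_dec25, 1L)
  expect_equal(cw2$snowmaking_before_feb28, 2L)  # cumulative through 28 Feb
  expect_equal(cw2$snowmaking, 2L)

  # all tmin missing: count is missing, not zero
  days3 <- uniform_winter_days()
  for (v in c("frost", "extreme_cold", "hwa_kill", "snowmaking")) {
    days3[[v]] <- NA
  }
  cw3 <- count_winter_indicators(days3, 2001)
  expect_true(is.na(cw3$frost))
  expect_equal(cw3$den_tmin, 0L)
  expect_equal(cw3$ice, 212L)

  # duplicate dates refuse
  days4 <- uniform_winter_days()
  days4$date[2] <- days4$date[1]
  expect_error(count_winter_indicators(days4, 2001), "duplicate")
})

test_that("per-winter partition and nesting invariants hold on random synthetic winters", {
  set.seed(101)
  n_checked <- 0L
  for (seed in 1:3) {
    s <- generate_daily_series(gen_params(
      n_years = 100, seed = seed,
      mean_temp = stats::runif(1, -2, 8), amplitude = stats::runif(1, 10, 20),
      noise_sd = stats::runif(1, 2, 6)
    ))
    m <- build_indicator_matrix(s)
    expect_true(all(m$frost >= m$ice))
    expect_true(all(m$hwa_kill <= m$extreme_cold))
    expect_true(all(m$extreme_cold <= m$snowmaking))
    expect_true(all(m$snowmaking <= m$frost))
    expect_true(all(m$snow_covered + m$bare_ground == m$den_swe))
    expect_true(all(m$frozen_ground + m$mud <= m$bare_ground))
    expect_true(all(m$rain_on_snow <= m$snow_covered))
    expect_true(all(m$snowmaking_before_dec25 <= m$snowmaking))
    expect_true(all(m$snowmaking_before_feb28 <= m$snowmaking))
    # thaw + ice + days at exactly 0 C partition the tmax-defined days
    wy <- assign_winter(s$records$date)
    zero_days <- tapply(s$records$tmax == 0, wy, sum)
    zero_days <- zero_days[match(m$winter_year, as.integer(names(zero_days)))]
    expect_true(all(m$thaw + m$ice + zero_days == m$den_tmax))
    n_checked <- n_checked + nrow(m)
  }
  expect_gte(n_checked, 300L)
})

test_that("lowering the extreme-cold threshold never increases its count", {
  s <- generate_daily_series(gen_params(n_years = 20, seed = 3))
  m1 <- build_indicator_matrix(s, thresholds = threshold_config(t_extreme_cold = -18))
  m2 <- build_indicator_matrix(s, thresholds = threshold_config(t_extreme_cold = -20))
  expect_true(all(m2$extreme_cold <= m1$extreme_cold))
})

test_that("the indicator matrix is complete for complete records and masks invalid winters", {
  s <- generate_daily_series(gen_params(n_years = 100, seed = 12))
  m <- build_indicator_matrix(s)
  expect_equal(nrow(m), 100L)
  expect_false(anyNA(m))

  # winter invalid for temperature only: temperature indicators missing,
  # SWE-dependent ones too (modeled SWE needs temperature), but a winter
  # invalid only for precipitation keeps its temperature indicators
  scr <- screen_completeness(s, qc_params(min_valid_winters = 2))
  v <- scr$winters
  v$valid_temp[v$winter_year == 1950] <- FALSE
  v$valid_prcp[v$winter_year == 1960] <- FALSE
  mv <- build_indicator_matrix(s, validity = v)
  r50 <- mv[mv$winter_year == 1950, ]
  expect_true(is.na(r50$frost) && is.na(r50$snow_covered))
  r60 <- mv[mv$winter_year == 1960, ]
  expect_false(is.na(r60$frost))
  expect_true(is.na(r60$snow_covered) && is.na(r60$rain_on_snow))

  # stations are independent: a two-station stack equals the per-station runs
  s2 <- generate_daily_series(gen_params(n_years = 100, seed = 13),
                              meta = station_meta("OTHER", 44, -80))
  m2 <- build_indicator_matrix(s2)
  stacked <- dplyr::bind_rows(m, m2)
  expect_identical(stacked[stacked$station_id == m$station_id[1], ], m)
})

test_that("count_winter_indicators and the matrix builder agree winter by winter", {
  s <- generate_daily_series(gen_params(n_years = 5, seed = 19))
  sw <- simulate_swe(s)
  m <- build_indicator_matrix(s, sw)
  part <- partition_precipitation((s$records$tmin + s$records$tmax) / 2,
                                  s$records$prcp)
  flags <- classify_day(tmax = s$records$tmax, tmin = s$records$tmin,
                        swe = sw$swe, rain = part$rain)
  flags$date <- s$records$date
  wy <- assign_winter(s$records$date)
  for (y in m$winter_year) {
    one <- count_winter_indicators(flags[!is.na(wy) & wy == y, ], y)
    expect_equal(m[m$winter_year == y, names(one)], one)
  }
})
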