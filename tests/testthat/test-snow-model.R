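test_that("precipitation phase partitioning is linear between thresholds and conservative", {
  p <- snow_params(t_snow = 0, t_rain = 2)
  expect_equal(partition_precipitation(-5, 10, p), tibble::tibble(rain = 0, snow = 10))
  expect_equal(partition_precipitation(5, 10, p), tibble::tibble(rain = 10, snow = 0))
  expect_equal(partition_precipitation(1, 10, p), tibble::tibble(rain = 5, snow = 5))

  set.seed(42)
  tavg <- stats::runif(500, -10, 10)
  prcp <- stats::rgamma(500, 0.7, scale = 8)
  part <- partition_precipitation(tavg, prcp, p)
  expect_equal(part$rain + part$snow, prcp)  # exact sum
  expect_true(all(part$rain >= 0 & part$snow >= 0))

  # missing mean temperature leaves the day undefined
  na_part <- partition_precipitation(NA, 10, p)
  expect_true(is.na(na_part$rain) && is.na(na_part$snow))

  # degenerate equal thresholds: step function, rain at/above
  pstep <- snow_params(t_snow = 1, t_rain = 1)
  expect_equal(partition_precipitation(c(0.9, 1, 1.1), 10, pstep)$rain,
               c(0, 10, 10))
})

test_that("daily stepping melts by degree-days, caps at the pack, and conserves mass", {
  p <- snow_params(ddf = 2.5, retain_frac = 0.05)
  st <- step_swe(swe_state(swe = 20), list(tmin = 2, tmax = 2, prcp = 0), p)
  expect_equal(st$fluxes$melt, 5)          # 2.5 mm/C/day * 2 C
  expect_equal(st$state$swe, 15)

  st2 <- step_swe(swe_state(swe = 1), list(tmin = 10, tmax = 10, prcp = 0), p)
  expect_equal(st2$fluxes$melt, 1)         # capped at the available mass
  expect_equal(st2$state$swe, 0)

  st3 <- step_swe(swe_state(swe = 30), list(tmin = -10, tmax = -10, prcp = 10), p)
  expect_equal(st3$state$swe, 40)          # accumulation only
  expect_equal(st3$fluxes$melt, 0)

  stna <- step_swe(swe_state(swe = 12), list(tmin = NA, tmax = 3, prcp = 0), p)
  expect_false(stna$defined)
  expect_equal(stna$state$swe, 12)         # state carried unchanged
})

test_that("mass balance is exact and stores stay within their invariants over randomized steps", {
  set.seed(7)
  p <- snow_params()
  state <- swe_state()
  resid_max <- 0
  for (i in seq_len(2000)) {
    tavg <- stats::runif(1, -15, 10)
    day <- list(tmin = tavg - 4, tmax = tavg + 4,
                prcp = if (stats::runif(1) < 0.4) stats::rgamma(1, 0.7, scale = 8) else 0)
    before <- state$swe + state$liquid_store
    st <- step_swe(state, day, p)
    delta <- st$state$swe + st$state$liquid_store - before
    resid <- delta - (st$fluxes$snow + st$fluxes$rain - st$fluxes$runoff)
    resid_max <- max(resid_max, abs(resid))
    expect_gte(st$state$swe, 0)
    expect_gte(st$state$liquid_store, 0)
    expect_lte(st$state$liquid_store, p$retain_frac * st$state$swe + 1e-12)
    state <- st$state
  }
  expect_lt(resid_max, 1e-9)
})

test_that("the compiled simulation agrees with the reference daily step", {
  s <- generate_daily_series(gen_params(n_years = 2, seed = 31))
  s <- inject_missingness(s, miss_spec(c(tmin = 0.05, prcp = 0.05)), seed = 5)
  p <- snow_params()
  sim <- simulate_swe(s, p)

  dp <- wintertrends:::date_parts(s$records$date)
  hydro <- dp$year + as.integer(dp$month >= 8L)
  state <- swe_state()
  for (i in seq_len(nrow(s$records))) {
    if (i > 1 && hydro[i] != hydro[i - 1]) state <- swe_state()
    st <- step_swe(state, as.list(s$records[i, ]), p)
    state <- st$state
    if (st$defined) {
      expect_equal(sim$swe[i], state$swe, tolerance = 1e-12)
    } else {
      expect_true(is.na(sim$swe[i]) && !sim$modeled[i])
    }
  }
})

test_that("simulated SWE depletes in closed form and stays zero in warm climates", {
  warm <- make_uniform_series("2000-09-01", "2001-06-30", tmin = 8, tmax = 16,
                              prcp = 5)
  expect_true(all(simulate_swe(warm)$swe == 0))

  # 50 mm event then +4 C at ddf 2.5 melts out on day 5 after the event
  ev <- make_uniform_series("2000-01-01", "2000-01-10", tmin = 4 - 4, tmax = 4 + 4,
                            prcp = 0)
  ev$records$tmin[1] <- -9
  ev$records$tmax[1] <- -1   # tavg -5: all snow
  ev$records$prcp[1] <- 50
  sim <- simulate_swe(ev, snow_params(ddf = 2.5, retain_frac = 0, refreeze_factor = 0))
  expect_equal(sim$swe[1], 50)
  expect_equal(sim$swe[6], 0)   # day 5 after the event
  expect_gt(sim$swe[5], 0)

  # full-simulation mass balance to 1e-9 mm: within each hydrological year
  # (pack starts empty) inputs minus runoff equal the final stores, where
  # the final liquid store is reconstructed from the daily flux balance
  s <- generate_daily_series(gen_params(n_years = 2, seed = 13))
  sim2 <- simulate_swe(s)
  dpx <- wintertrends:::date_parts(s$records$date)
  hy <- dpx$year + as.integer(dpx$month >= 8L)
  for (y in unique(hy)) {
    i <- hy == y
    inputs <- sum(sim2$snow[i] + sim2$rain[i]) - sum(sim2$runoff[i])
    liquid_end <- sum(sim2$melt[i] + sim2$rain[i] - sim2$runoff[i] - sim2$refreeze[i])
    swe_end <- sim2$swe[max(which(i))]
    expect_lt(abs(inputs - (swe_end + liquid_end)), 1e-9)
  }
})

test_that("raising the melt factor never increases SWE on any day", {
  s <- generate_daily_series(gen_params(n_years = 3, seed = 17))
  sims <- lapply(c(1, 2.5, 5), function(d) simulate_swe(s, snow_params(ddf = d))$swe)
  expect_true(all(sims[[1]] >= sims[[2]] - 1e-9))
  expect_true(all(sims[[2]] >= sims[[3]] - 1e-9))
})

test_that("a pack at the melt base with no precipitation is steady", {
  s <- make_uniform_series("2000-09-01", "2000-12-01", tmin = -4, tmax = 4,
                           prcp = 0)  # tavg = 0 = t_melt
  sim <- simulate_swe(s, init = swe_state(swe = 30))
  expect_true(all(sim$swe == 30))
})

test_that("grid calibration recovers generating parameters and breaks ties toward defaults", {
  truth <- snow_params(ddf = 5, t_melt = 1)
  s <- generate_daily_series(gen_params(n_years = 4, seed = 23), snow = truth)
  s$records$snow_depth <- simulate_swe(s, truth)$swe   # model-generated observations
  grid <- expand.grid(ddf = c(1, 2.5, 5), t_melt = c(-1, 0, 1))
  cal <- calibrate_snow_params(s, grid)
  expect_equal(cal$agreement, 1.0)
  expect_equal(cal$params$ddf, 5)
  expect_equal(cal$params$t_melt, 1)

  # all-zero observed depth in a warm series: every candidate ties at 1,
  # defaults win
  warm <- make_uniform_series("2000-06-01", "2000-07-31", tmin = 10, tmax = 20,
                              prcp = 3, snow_depth = 0)
  cal2 <- calibrate_snow_params(warm, grid)
  expect_equal(cal2$agreement, 1.0)
  expect_equal(cal2$params$ddf, snow_params()$ddf)
  expect_equal(cal2$params$t_melt, snow_params()$t_melt)

  # no observed depth at all: calibration error
  none <- make_uniform_series("2000-01-01", "2000-02-01")
  expect_error(calibrate_snow_params(none, grid), "no usable")
})
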