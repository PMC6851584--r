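# Experiment drivers shared by the acceptance tests. Each runs the package
# end to end on synthetic stations with known ground truth.

# Frost-day counts per winter through the package's classification path.
frost_count_series <- function(series) {
  wy <- assign_winter(series$records$date)
  frost <- classify_day(tmax = series$records$tmax,
                        tmin = series$records$tmin)$frost
  keep <- !is.na(wy) & !is.na(frost)
  counts <- tapply(frost[keep], wy[keep], sum)
  list(counts = as.numeric(counts), years = as.integer(names(counts)))
}

# One replicate of the trend-recovery experiment: `n_stations` stations with
# the same injected tmin trend; returns the first station's Sen slope of
# frost days and the regional p value across all stations.
frost_recovery_replicate <- function(rep_seed, trend_tmin, n_stations = 5,
                                     n_years = 100) {
  blocks <- list()
  slope1 <- NA_real_
  for (k in seq_len(n_stations)) {
    s <- generate_daily_series(gen_params(n_years = n_years,
                                          seed = rep_seed * 1000L + k,
                                          trend_tmin = trend_tmin))
    fc <- frost_count_series(s)
    if (k == 1L) slope1 <- sen_slope(fc$counts, fc$years)
    blocks[[k]] <- data.frame(block = sprintf("S%d", k), time = fc$years,
                              value = fc$counts)
  }
  rk <- regional_kendall(do.call(rbind, blocks))
  list(sen_slope = slope1, regional_p = rk$p)
}

# One seed of the three-subregion experiment: 9 stations (3 per subregion),
# warming injected on tmin in the west and east only; returns whether the
# regional frost-day verdicts show the expected pattern (significant
# negative in west and east, non-significant in central).
subregion_pattern_replicate <- function(seed, n_years = 100,
                                        trend_warm = 1.0) {
  roster <- tibble::tibble(
    station_id = sprintf("%s_%d", rep(c("WEST", "CENTRAL", "EAST"), each = 3),
                         rep(1:3, 3)),
    longitude = rep(c(-90, -82, -72), each = 3) + rep(c(-0.5, 0, 0.5), 3),
    trend = rep(c(trend_warm, 0, trend_warm), each = 3)
  )
  mats <- lapply(seq_len(nrow(roster)), function(i) {
    st <- roster[i, ]
    s <- generate_daily_series(
      gen_params(n_years = n_years,
                 seed = wintertrends:::station_seed(seed, st$station_id),
                 trend_tmin = st$trend),
      meta = station_meta(st$station_id, 45, st$longitude)
    )
    scr <- screen_completeness(s, qc_params(min_valid_winters = 2))
    build_indicator_matrix(s, validity = scr$winters)
  })
  im <- dplyr::bind_rows(mats)
  stations <- tibble::tibble(station_id = roster$station_id, latitude = 45,
                             longitude = roster$longitude)
  reg <- regional_trends(im, stations, indicators = "frost")
  verdict <- function(region) {
    r <- reg[reg$subregion == region, ]
    c(sig = r$significant, neg = !is.na(r$sen_slope) && r$sen_slope < 0)
  }
  w <- verdict("west"); ce <- verdict("central"); e <- verdict("east")
  list(
    pattern = w[["sig"]] && w[["neg"]] && e[["sig"]] && e[["neg"]] && !ce[["sig"]],
    west_sig_neg = w[["sig"]] && w[["neg"]],
    east_sig_neg = e[["sig"]] && e[["neg"]],
    central_ns = !ce[["sig"]]
  )
}
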