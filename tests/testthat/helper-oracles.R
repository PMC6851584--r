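# Independent brute-force oracles and small fixture builders shared by the
# module and acceptance tests. The oracles deliberately use naive double
# loops so they share no code with the implementation they check.

# Kendall S by explicit double loop.
bf_kendall_S <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i])
    }
  }
  s
}

# All pairwise slopes by explicit double loop (distinct times only).
bf_pairwise_slopes <- function(x, t) {
  out <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (t[j] != t[i]) out <- c(out, (x[j] - x[i]) / (t[j] - t[i]))
    }
  }
  out
}

# Untied Mann-Kendall variance (for the tie-correction inequality).
bf_var_untied <- function(n) n * (n - 1) * (2 * n + 5) / 18

# Day-classification truth table evaluated directly from the indicator
# definitions, one day at a time, without reusing classify_day's code.
bf_classify_day <- function(tmax, tmin, swe, rain) {
  u <- function(cond, ...) {
    inputs <- c(...)
    if (any(is.na(inputs))) NA else cond
  }
  snow_cov <- u(swe > 0, swe)
  list(
    thaw = u(tmax > 0, tmax),
    ice = u(tmax < 0, tmax),
    frost = u(tmin < 0, tmin),
    extreme_cold = u(tmin < -18, tmin),
    hwa_kill = u(tmin < -30, tmin),
    snowmaking = u(tmin < -5, tmin),
    snow_covered = snow_cov,
    bare_ground = u(swe == 0, swe),
    rain_on_snow = u(rain > 0 && swe > 0, rain, swe),
    frozen_ground = u(tmax < 0 && swe == 0, tmax, swe),
    mud = u(tmax > 0 && swe == 0, tmax, swe)
  )
}

# A station series with constant daily values over a date range.
make_uniform_series <- function(from, to, tmin = -10, tmax = -5, prcp = 0,
                                snowfall = 0, snow_depth = NA_real_,
                                id = "TEST1", lon = -75) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  station_series(
    tibble::tibble(date = dates, tmin = tmin, tmax = tmax, prcp = prcp,
                   snowfall = snowfall, snow_depth = snow_depth),
    station_meta(id, 45, lon)
  )
}

# Random annual count-like series with ties, for oracle comparisons.
random_tied_series <- function(n) {
  round(stats::rnorm(n, mean = 10, sd = 2))
}
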