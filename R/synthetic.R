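#' Parameters of the synthetic daily-weather generator
#'
#' Describes a mid-latitude station climate for the generator: a sinusoidal
#' seasonal temperature cycle (365.25-day period evaluated on real calendar
#' dates, minimum at `coldest_doy`), AR(1) day-to-day temperature noise
#' shared by `tmin` and `tmax` (which keeps `tmin <= tmax` by construction),
#' independent linear trends on `tmin` and `tmax`, and wet-day precipitation
#' with Bernoulli occurrence and Gamma amounts.
#'
#' @param n_years Number of complete winters to generate (>= 2). The record
#'   spans whole hydrological years: 1 August `start_year` through 31 July
#'   `start_year + n_years`, so winters `start_year + 1` ...
#'   `start_year + n_years` are complete.
#' @param start_year First calendar year (the record starts 1 August of it).
#' @param mean_temp Annual mean temperature, degrees C.
#' @param amplitude Seasonal half-range, degrees C (>= 0).
#' @param coldest_doy Day of year of the seasonal minimum (default 15 = mid
#'   January).
#' @param diurnal_range `tmax - tmin`, degrees C (> 0).
#' @param noise_sd Stationary (marginal) standard deviation of the AR(1)
#'   temperature noise, degrees C.
#' @param ar1 Lag-1 autocorrelation of the noise, in \[0, 1).
#' @param trend_tmin,trend_tmax Linear trends, degrees C per decade.
#' @param p_wet Wet-day probability, in \[0, 1\].
#' @param wet_gamma_shape,wet_gamma_scale Gamma parameters of wet-day
#'   precipitation amount (mm).
#' @param seed Integer seed; the same parameters always generate the same
#'   series.
#' @return A list of class `gen_params`.
#' @export
gen_params <- function(n_years = 100, start_year = 1916, mean_temp = 5,
                       amplitude = 15, coldest_doy = 15, diurnal_range = 8,
                       noise_sd = 4, ar1 = 0.6, trend_tmin = 0, trend_tmax = 0,
                       p_wet = 0.35, wet_gamma_shape = 0.7,
                       wet_gamma_scale = 8, seed = 1L) {
  stopifnot(
    n_years >= 2, amplitude >= 0, diurnal_range > 0, noise_sd >= 0,
    ar1 >= 0, ar1 < 1, p_wet >= 0, p_wet <= 1,
    wet_gamma_shape > 0, wet_gamma_scale > 0
  )
  structure(
    list(n_years = as.integer(n_years), start_year = as.integer(start_year),
         mean_temp = mean_temp, amplitude = amplitude,
         coldest_doy = coldest_doy, diurnal_range = diurnal_range,
         noise_sd = noise_sd, ar1 = ar1,
         trend_tmin = trend_tmin, trend_tmax = trend_tmax,
         p_wet = p_wet, wet_gamma_shape = wet_gamma_shape,
         wet_gamma_scale = wet_gamma_scale, seed = as.integer(seed)),
    class = "gen_params"
  )
}

#' Noiseless seasonal mean temperature for given dates
#'
#' The deterministic part of the generator's daily mean temperature,
#' excluding trends: `mean_temp - amplitude * cos(2 * pi * (doy -
#' coldest_doy) / 365.25)` evaluated on real calendar day-of-year, so the
#' minimum stays aligned with `coldest_doy` across leap years.
#'
#' @param dates A `Date` vector.
#' @param params A [gen_params()].
#' @return Numeric vector of daily mean temperatures, degrees C.
#' @export
seasonal_mean_temp <- function(dates, params) {
  doy <- date_parts(dates)$doy
  params$mean_temp -
    params$amplitude * cos(2 * pi * (doy - params$coldest_doy) / 365.25)
}

#' Generate a synthetic daily station series
#'
#' Produces a complete daily record with the structure described by
#' [gen_params()]: seasonal cycle plus AR(1) noise on the daily mean
#' temperature, `tmax = tmean + diurnal_range / 2` and `tmin = tmean -
#' diurnal_range / 2` with their own linear trends, wet-day precipitation,
#' and snowfall as the snow component of [partition_precipitation()] at the
#' given snow parameters (converted to mm solid with a 10:1 fresh-snow
#' ratio). Snow depth is left missing by default, since downstream analyses
#' use modeled SWE; `snow_depth = "model"` stores the modeled SWE as a
#' surrogate observed depth for gap-fill and calibration tests. Output is
#' bit-identical for identical parameters.
#'
#' @param params A [gen_params()].
#' @param meta Optional [station_meta()]; a default synthetic one is built
#'   from the seed.
#' @param snow_depth `"none"` (default) or `"model"`.
#' @param snow A [snow_params()] used for snowfall partitioning (and depth
#'   when `snow_depth = "model"`).
#' @return A `station_series`.
#' @export
#' @examples
#' s <- generate_daily_series(gen_params(n_years = 3, seed = 42))
#' s
generate_daily_series <- function(params, meta = NULL,
                                  snow_depth = c("none", "model"),
                                  snow = snow_params()) {
  stopifnot(inherits(params, "gen_params"))
  snow_depth <- match.arg(snow_depth)
  if (is.null(meta)) {
    meta <- station_meta(sprintf("SYN%06d", params$seed %% 1000000L), 45, -75)
  }
  dates <- seq(as.Date(sprintf("%d-08-01", params$start_year)),
               as.Date(sprintf("%d-07-31", params$start_year + params$n_years)),
               by = "day")
  n <- length(dates)
  years_elapsed <- as.numeric(dates - dates[1]) / 365.25

  base <- seasonal_mean_temp(dates, params)
  noise <- local_seed(params$seed, {
    innov_sd <- params$noise_sd * sqrt(1 - params$ar1^2)
    eps <- stats::rnorm(n, sd = innov_sd)
    if (params$ar1 > 0) {
      as.numeric(stats::filter(eps, params$ar1, method = "recursive")) +
        # start the recursion in the stationary distribution
        params$ar1^(seq_len(n)) * stats::rnorm(1, sd = params$noise_sd)
    } else {
      eps
    }
  })
  wet_amt <- local_seed(params$seed + 1L, {
    wet <- stats::runif(n) < params$p_wet
    amt <- numeric(n)
    amt[wet] <- stats::rgamma(sum(wet), shape = params$wet_gamma_shape,
                              scale = params$wet_gamma_scale)
    amt
  })

  tmean <- base + noise
  tmax <- tmean + params$diurnal_range / 2 + params$trend_tmax / 10 * years_elapsed
  tmin <- tmean - params$diurnal_range / 2 + params$trend_tmin / 10 * years_elapsed
  tavg <- (tmin + tmax) / 2
  part <- partition_precipitation(tavg, wet_amt, snow)

  # values recorded at the 0.1 C / 0.1 mm resolution of daily archives, so
  # generator output survives a write/read round trip bit-identically
  rec <- tibble::tibble(
    date = dates, tmin = round(tmin, 1), tmax = round(tmax, 1),
    prcp = round(wet_amt, 1),
    snowfall = round(10 * part$snow, 1),  # mm solid, 10:1 fresh-snow ratio
    snow_depth = NA_real_
  )
  out <- station_series(rec, meta, check = FALSE)
  if (snow_depth == "model") {
    out$records$snow_depth <- round(simulate_swe(out, snow)$swe, 1)
  }
  out
}

#' Missingness specification for synthetic series
#'
#' @param frac_missing Named numeric vector of target missing fractions in
#'   \[0, 1\] for any of `tmin`, `tmax`, `prcp`, `snowfall`, `snow_depth`
#'   (unnamed variables get 0).
#' @param block_length_mean Mean length (days) of the geometric missing-block
#'   lengths (>= 1).
#' @param unreported_zero_snow If `TRUE`, every day whose true snow depth is
#'   exactly zero has its depth set missing — emulating observers who leave
#'   the field blank instead of recording zero when no snow is on the ground.
#'   Days with snow on the ground are never blanked by this mechanism.
#' @return A list of class `miss_spec`.
#' @export
miss_spec <- function(frac_missing = c(), block_length_mean = 3,
                      unreported_zero_snow = FALSE) {
  vars <- c("tmin", "tmax", "prcp", "snowfall", "snow_depth")
  fm <- stats::setNames(rep(0, length(vars)), vars)
  if (length(frac_missing) > 0L) {
    stopifnot(!is.null(names(frac_missing)),
              all(names(frac_missing) %in% vars),
              all(frac_missing >= 0 & frac_missing <= 1))
    fm[names(frac_missing)] <- frac_missing
  }
  stopifnot(block_length_mean >= 1)
  structure(
    list(frac_missing = fm, block_length_mean = block_length_mean,
         unreported_zero_snow = isTRUE(unreported_zero_snow)),
    class = "miss_spec"
  )
}

#' Inject missingness into a station series
#'
#' Masks values in geometric-length blocks at random positions,
#' per variable, until each variable's realised missing fraction reaches its
#' target; with `unreported_zero_snow`, additionally blanks the snow depth
#' of every true-zero-depth day. The input series is not modified.
#'
#' @param series A `station_series`.
#' @param spec A [miss_spec()].
#' @param seed Integer seed for block placement.
#' @return A new `station_series` with values masked to `NA`.
#' @export
inject_missingness <- function(series, spec, seed = 1L) {
  stopifnot(inherits(series, "station_series"), inherits(spec, "miss_spec"))
  rec <- series$records
  n <- nrow(rec)
  local_seed(as.integer(seed), {
    for (v in names(spec$frac_missing)) {
      target <- spec$frac_missing[[v]]
      if (target <= 0) next
      miss <- is.na(rec[[v]])
      goal <- ceiling(target * n)
      guard <- 0L
      while (sum(miss) < goal && guard < 100000L) {
        len <- stats::rgeom(1, prob = 1 / spec$block_length_mean) + 1L
        start <- sample.int(n, 1L)
        idx <- start:min(n, start + len - 1L)
        # trim so we land near, not past, the target
        overshoot <- sum(!miss[idx]) - (goal - sum(miss))
        if (overshoot > 0) idx <- idx[seq_len(length(idx) - overshoot)]
        miss[idx] <- TRUE
        guard <- guard + 1L
      }
      rec[[v]][miss] <- NA_real_
    }
    NULL
  })
  if (spec$unreported_zero_snow) {
    zero <- !is.na(rec$snow_depth) & rec$snow_depth == 0
    rec$snow_depth[zero] <- NA_real_
  }
  station_series(rec, series$meta, check = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic per-station seed substream: adding a station to a run never
# perturbs the weather of the others.
station_seed <- function(global_seed, station_id) {
  h <- 0
  for (k in utf8ToInt(station_id)) h <- (h * 131 + k) %% 1013904223
  as.integer((as.numeric(global_seed) * 2654435761 + h) %% 2147483647)
}
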