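#' Indicator thresholds and winter window
#'
#' All day-classification thresholds in one configurable object. Defaults are
#' the standard definitions used for winter climate-change indicators in
#' northeastern North American forests:
#'
#' * Thaw day: `tmax > 0` C; Ice day: `tmax < 0` C; Frost day: `tmin < 0` C
#'   (ETCCDI definitions).
#' * Extreme cold day (= pine beetle kill day): `tmin < -18` C.
#' * Hemlock woolly adelgid kill day: `tmin < -30` C.
#' * Snowmaking day (= mosquito kill day): `tmin < -5` C, also counted within
#'   two ski-season windows (before 25 December; through 28 February).
#' * Snow covered day: modeled SWE `> 0` mm; bare ground day: SWE `= 0` mm.
#' * Rain-on-snow day: liquid (rain) precipitation `> 0` mm on a snow-covered
#'   day.
#' * Bare ground ice day (frozen ground) and bare ground thaw day (mud):
#'   ice/thaw day with bare ground.
#'
#' All inequalities are strict. Winter spans 1 November - 31 May (the dormant
#' season) and is labeled by its ending calendar year.
#'
#' @param t_thaw,t_ice,t_frost,t_extreme_cold,t_hwa_kill,t_snowmaking
#'   Temperature thresholds, degrees C.
#' @param snow_cover_mm SWE above which a day counts as snow covered (mm);
#'   0 means any modeled snow at all (an optional trace cutoff).
#' @param christmas_inclusive If `TRUE`, 25 December itself counts in the
#'   early-season snowmaking window; default `FALSE` (strictly before).
#' @param feb_window_inclusive If `TRUE` (default), 28 February counts in the
#'   late window (29 February never does).
#' @param winter_start,winter_end `"MM-DD"` strings delimiting the winter
#'   window; the start must fall in July-December and the end in January-June.
#'
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(t_thaw = 0, t_ice = 0, t_frost = 0,
                             t_extreme_cold = -18, t_hwa_kill = -30,
                             t_snowmaking = -5, snow_cover_mm = 0,
                             christmas_inclusive = FALSE,
                             feb_window_inclusive = TRUE,
                             winter_start = "11-01", winter_end = "05-31") {
  stopifnot(
    t_hwa_kill < t_extreme_cold, t_extreme_cold < t_snowmaking,
    t_snowmaking < t_frost, snow_cover_mm >= 0
  )
  ws <- parse_monthday(winter_start)
  we <- parse_monthday(winter_end)
  if (ws$month < 7L) stop("winter_start must fall in July-December")
  if (we$month > 6L) stop("winter_end must fall in January-June")
  structure(
    list(
      t_thaw = t_thaw, t_ice = t_ice, t_frost = t_frost,
      t_extreme_cold = t_extreme_cold, t_hwa_kill = t_hwa_kill,
      t_snowmaking = t_snowmaking, snow_cover_mm = snow_cover_mm,
      christmas_inclusive = christmas_inclusive,
      feb_window_inclusive = feb_window_inclusive,
      winter_start = ws, winter_end = we
    ),
    class = "threshold_config"
  )
}

parse_monthday <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2})-([0-9]{1,2})$", x))[[1]]
  if (length(m) != 3L) stop("expected 'MM-DD', got: ", x)
  list(month = as.integer(m[2]), day = as.integer(m[3]))
}

#' Map dates to winters
#'
#' A winter runs 1 November - 31 May and is labeled by the calendar year in
#' which it ends: November and December belong to the following year's
#' winter, January-May to their own year's, and June-October to no winter.
#'
#' @param dates A `Date` vector.
#' @param thresholds A [threshold_config()] (for a non-default window).
#' @return Integer vector of winter labels, `NA` outside the window.
#' @export
#' @examples
#' assign_winter(as.Date(c("2000-11-01", "2001-05-31", "2001-06-15")))
assign_winter <- function(dates, thresholds = threshold_config()) {
  dates <- as.Date(dates)
  dp <- date_parts(dates)
  year <- dp$year
  key <- dp$month * 100L + dp$day
  start_key <- thresholds$winter_start$month * 100L + thresholds$winter_start$day
  end_key <- thresholds$winter_end$month * 100L + thresholds$winter_end$day
  out <- rep(NA_integer_, length(dates))
  out[key >= start_key] <- year[key >= start_key] + 1L
  out[key <= end_key] <- year[key <= end_key]
  out
}

#' Number of calendar days in a winter window
#'
#' @param winter_year Integer vector of winter labels (ending year).
#' @param thresholds A [threshold_config()].
#' @return Integer vector: 212 for ordinary winters, 213 when the ending year
#'   is a leap year (the default window contains that year's February).
#' @export
winter_length <- function(winter_year, thresholds = threshold_config()) {
  y <- as.integer(winter_year)
  start <- as.Date(sprintf("%d-%02d-%02d", y - 1L,
                           thresholds$winter_start$month,
                           thresholds$winter_start$day))
  end <- as.Date(sprintf("%d-%02d-%02d", y,
                         thresholds$winter_end$month,
                         thresholds$winter_end$day))
  as.integer(end - start) + 1L
}

# Sequence of all dates in one winter window.
winter_window <- function(winter_year, thresholds = threshold_config()) {
  y <- as.integer(winter_year)
  seq(
    as.Date(sprintf("%d-%02d-%02d", y - 1L, thresholds$winter_start$month,
                    thresholds$winter_start$day)),
    as.Date(sprintf("%d-%02d-%02d", y, thresholds$winter_end$month,
                    thresholds$winter_end$day)),
    by = "day"
  )
}

#' Classify days against the indicator thresholds
#'
#' Vectorised day classification. Each flag is `TRUE`/`FALSE` when its
#' required inputs are present and `NA` (undefined) otherwise; compound flags
#' are undefined whenever any required input is missing. All comparisons are
#' strict, exactly as in the indicator definitions: a day with `tmax = 0`
#' exactly is neither a thaw day nor an ice day.
#'
#' `rain` is the liquid component of that day's precipitation as returned by
#' [partition_precipitation()]; `swe` is the modeled snow water equivalent
#' (use `NA` where the snow model is undefined).
#'
#' @param tmax,tmin Daily temperature extremes, degrees C (may be `NA`).
#' @param swe Modeled SWE, mm (may be `NA`).
#' @param rain Liquid precipitation, mm (may be `NA`).
#' @param thresholds A [threshold_config()].
#' @return A tibble of logical columns: `thaw`, `ice`, `frost`,
#'   `extreme_cold`, `hwa_kill`, `snowmaking`, `snow_covered`, `bare_ground`,
#'   `rain_on_snow`, `frozen_ground`, `mud`.
#' @export
#' @examples
#' classify_day(tmax = -2, tmin = -6, swe = 10, rain = 0)
classify_day <- function(tmax, tmin, swe = NA_real_, rain = NA_real_,
                         thresholds = threshold_config()) {
  n <- max(length(tmax), length(tmin), length(swe), length(rain))
  tmax <- rep_len(as.numeric(tmax), n)
  tmin <- rep_len(as.numeric(tmin), n)
  swe <- rep_len(as.numeric(swe), n)
  rain <- rep_len(as.numeric(rain), n)

  thaw <- tmax > thresholds$t_thaw
  ice <- tmax < thresholds$t_ice
  frost <- tmin < thresholds$t_frost
  extreme_cold <- tmin < thresholds$t_extreme_cold
  hwa_kill <- tmin < thresholds$t_hwa_kill
  snowmaking <- tmin < thresholds$t_snowmaking
  snow_covered <- swe > thresholds$snow_cover_mm
  bare_ground <- !snow_covered

  rain_on_snow <- rain > 0 & snow_covered
  rain_on_snow[is.na(rain) | is.na(swe)] <- NA
  frozen_ground <- ice & bare_ground
  frozen_ground[is.na(tmax) | is.na(swe)] <- NA
  mud <- thaw & bare_ground
  mud[is.na(tmax) | is.na(swe)] <- NA

  tibble::tibble(
    thaw = thaw, ice = ice, frost = frost, extreme_cold = extreme_cold,
    hwa_kill = hwa_kill, snowmaking = snowmaking,
    snow_covered = snow_covered, bare_ground = bare_ground,
    rain_on_snow = rain_on_snow, frozen_ground = frozen_ground, mud = mud
  )
}

indicator_names <- function() {
  c("thaw", "ice", "frost", "extreme_cold", "hwa_kill", "snowmaking",
    "snowmaking_before_dec25", "snowmaking_before_feb28",
    "snow_covered", "bare_ground", "rain_on_snow", "frozen_ground", "mud")
}

# denominator column backing each indicator count
indicator_denominators <- function() {
  c(thaw = "den_tmax", ice = "den_tmax", frost = "den_tmin",
    extreme_cold = "den_tmin", hwa_kill = "den_tmin", snowmaking = "den_tmin",
    snowmaking_before_dec25 = "den_snowmaking_dec25",
    snowmaking_before_feb28 = "den_snowmaking_feb28",
    snow_covered = "den_swe", bare_ground = "den_swe",
    rain_on_snow = "den_ros", frozen_ground = "den_tmax_swe",
    mud = "den_tmax_swe")
}

#' Count indicator days within one winter
#'
#' Sums the day flags of one winter into indicator counts, together with the
#' valid-day denominator of each required input set. A count whose
#' denominator is zero (no day had the required inputs) is reported as `NA`,
#' never as zero. The two snowmaking windows count snowmaking days falling
#' before 25 December of the winter's opening year and through 28 February of
#' its closing year (boundary conventions from the [threshold_config()]).
#'
#' @param days A tibble with a `date` column plus the flag columns produced
#'   by [classify_day()]. All dates must belong to `winter_year`; duplicate
#'   dates are an error.
#' @param winter_year Integer winter label (ending year).
#' @param thresholds A [threshold_config()].
#' @return A one-row tibble: `winter_year`, `n_days` (window length), the 13
#'   indicator counts, and denominators `den_tmax`, `den_tmin`, `den_swe`,
#'   `den_tmax_swe`, `den_ros`, `den_snowmaking_dec25`,
#'   `den_snowmaking_feb28`.
#' @export
count_winter_indicators <- function(days, winter_year,
                                    thresholds = threshold_config()) {
  winter_year <- as.integer(winter_year)
  if (anyDuplicated(days$date)) stop("duplicate dates within winter ", winter_year)
  wy <- assign_winter(days$date, thresholds)
  if (!all(wy == winter_year, na.rm = TRUE) || anyNA(wy)) {
    stop("days outside winter ", winter_year, " passed to count_winter_indicators")
  }
  winter_indicator_counts(days, wy, thresholds)
}

# Vectorised winter aggregation shared by count_winter_indicators (one
# winter) and build_indicator_matrix (all winters at once): rowsum over the
# winter grouping, with a count set NA whenever its valid-day denominator
# is zero.
winter_indicator_counts <- function(days, wy, thresholds) {
  flag_cols <- c("thaw", "ice", "frost", "extreme_cold", "hwa_kill",
                 "snowmaking", "snow_covered", "bare_ground", "rain_on_snow",
                 "frozen_ground", "mud")
  fm <- vapply(flag_cols, function(v) as.numeric(days[[v]]),
               numeric(nrow(days)))
  if (nrow(days) == 1L) fm <- matrix(fm, nrow = 1L, dimnames = list(NULL, flag_cols))

  # cumulative snowmaking windows, by month-day key (Feb 29 never in the
  # late window when its bound is 28 Feb)
  dp <- date_parts(days$date)
  key <- dp$month * 100L + dp$day
  start_key <- thresholds$winter_start$month * 100L +
    thresholds$winter_start$day
  opening <- key >= start_key
  in_dec <- opening & if (thresholds$christmas_inclusive) key <= 1225L else key < 1225L
  in_feb <- opening | if (thresholds$feb_window_inclusive) key <= 228L else key < 228L
  sm_dec <- ifelse(in_dec, fm[, "snowmaking"], NA)
  sm_feb <- ifelse(in_feb, fm[, "snowmaking"], NA)
  fm <- cbind(fm, snowmaking_before_dec25 = sm_dec,
              snowmaking_before_feb28 = sm_feb)

  grp <- as.character(wy)
  counts <- rowsum(fm, grp, na.rm = TRUE)
  dens <- rowsum((!is.na(fm)) * 1, grp)
  counts[dens == 0] <- NA
  years <- as.integer(rownames(counts))
  ord <- order(years)
  counts <- counts[ord, , drop = FALSE]
  dens <- dens[ord, , drop = FALSE]
  years <- years[ord]

  out <- tibble::tibble(winter_year = years,
                        n_days = winter_length(years, thresholds))
  for (v in indicator_names()) out[[v]] <- as.integer(counts[, v])
  out$den_tmax <- as.integer(dens[, "thaw"])
  out$den_tmin <- as.integer(dens[, "frost"])
  out$den_swe <- as.integer(dens[, "snow_covered"])
  out$den_tmax_swe <- as.integer(dens[, "frozen_ground"])
  out$den_ros <- as.integer(dens[, "rain_on_snow"])
  out$den_snowmaking_dec25 <- as.integer(dens[, "snowmaking_before_dec25"])
  out$den_snowmaking_feb28 <- as.integer(dens[, "snowmaking_before_feb28"])
  out
}

#' Indicator counts for every winter of a station
#'
#' Aligns a station's daily records with its modeled SWE series, classifies
#' every winter day, and returns one row of indicator counts per winter. This
#' table (stacked across stations) is the single input to the trend
#' statistics.
#'
#' Liquid precipitation for the rain-on-snow indicator is the rain component
#' of [partition_precipitation()] at the snow model's phase thresholds. When
#' `validity` (from [screen_completeness()]) is supplied, winters that fail
#' the temperature screen have all temperature-dependent indicators set
#' missing, and winters failing either screen have the SWE-dependent
#' indicators set missing (modeled SWE needs both temperature and
#' precipitation); winters absent from the validity table are dropped.
#'
#' @param series A `station_series`.
#' @param swe A SWE series from [simulate_swe()]; computed on the fly if
#'   `NULL`. Must contain every record date (a mismatch is an error).
#' @param validity Optional per-winter validity tibble from
#'   [screen_completeness()].
#' @param thresholds A [threshold_config()].
#' @param snow A [snow_params()] (for SWE simulation and rain partitioning).
#' @return A tibble: `station_id`, then one [count_winter_indicators()] row
#'   per winter.
#' @export
build_indicator_matrix <- function(series, swe = NULL, validity = NULL,
                                   thresholds = threshold_config(),
                                   snow = snow_params()) {
  assert_clean_series(series)
  rec <- series$records
  if (is.null(swe)) swe <- simulate_swe(series, snow)
  idx <- match(as.numeric(rec$date), as.numeric(swe$date))
  if (anyNA(idx)) stop("SWE series does not cover all record dates (date misalignment)")
  swe_day <- swe$swe[idx]

  tavg <- (rec$tmin + rec$tmax) / 2
  part <- partition_precipitation(tavg, rec$prcp, snow)

  flags <- classify_day(tmax = rec$tmax, tmin = rec$tmin, swe = swe_day,
                        rain = part$rain, thresholds = thresholds)
  flags$date <- rec$date
  wy <- assign_winter(rec$date, thresholds)
  keep <- !is.na(wy)
  flags <- flags[keep, , drop = FALSE]
  wy <- wy[keep]
  if (nrow(flags) == 0L) {
    return(tibble::tibble(station_id = character()))
  }
  counts <- winter_indicator_counts(flags, wy, thresholds)
  if (!is.null(validity)) {
    counts <- counts[counts$winter_year %in% validity$winter_year, , drop = FALSE]
    v <- validity[match(counts$winter_year, validity$winter_year), ]
    temp_ind <- c("thaw", "ice", "frost", "extreme_cold", "hwa_kill",
                  "snowmaking", "snowmaking_before_dec25", "snowmaking_before_feb28")
    swe_ind <- c("snow_covered", "bare_ground", "rain_on_snow",
                 "frozen_ground", "mud")
    for (col in temp_ind) counts[[col]][!v$valid_temp] <- NA_integer_
    for (col in swe_ind) counts[[col]][!(v$valid_temp & v$valid_prcp)] <- NA_integer_
  }
  dplyr::bind_cols(tibble::tibble(station_id = series$meta$station_id), counts)
}
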