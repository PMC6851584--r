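#' Completeness screening parameters
#'
#' Per-winter and per-station record-completeness thresholds. A winter is
#' usable for a variable only if its missing fraction over the full 1 Nov -
#' 31 May window stays at or below the threshold; a station is retained only
#' if enough winters are usable, which favours the long (century-scale)
#' records needed for trend detection. The 10% per-winter rule is a common
#' climatological completeness convention; both it and the station minimum
#' are configuration, not constants.
#'
#' @param max_missing_frac_temp Maximum per-winter missing fraction for
#'   temperature (applied to `tmin` and `tmax` separately; both must pass).
#' @param max_missing_frac_prcp Maximum per-winter missing fraction for
#'   precipitation.
#' @param min_valid_winters Minimum number of winters valid for at least one
#'   of temperature or precipitation for the station to pass (>= 2); the
#'   comparison is inclusive (`>=`).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(max_missing_frac_temp = 0.10,
                      max_missing_frac_prcp = 0.10,
                      min_valid_winters = 90) {
  stopifnot(
    max_missing_frac_temp >= 0, max_missing_frac_temp <= 1,
    max_missing_frac_prcp >= 0, max_missing_frac_prcp <= 1,
    min_valid_winters >= 2
  )
  structure(
    list(max_missing_frac_temp = max_missing_frac_temp,
         max_missing_frac_prcp = max_missing_frac_prcp,
         min_valid_winters = as.integer(min_valid_winters)),
    class = "qc_params"
  )
}

#' Screen a station's winters for record completeness
#'
#' Computes per-winter missing fractions over the full winter window (days
#' absent from the record count as missing) and flags each winter's validity
#' for temperature and precipitation; the station passes if at least
#' `min_valid_winters` winters are valid for temperature and/or
#' precipitation (inclusive bound). Verdicts are pure functions of the
#' series and thresholds.
#'
#' @param series A `station_series` (must have a clean date axis).
#' @param qc A [qc_params()].
#' @param thresholds A [threshold_config()] (for the winter window).
#' @return A list: `winters` (tibble with `station_id`, `winter_year`,
#'   missing fractions, `valid_temp`, `valid_prcp`), `n_valid` (winters valid
#'   for either variable) and `station_pass` (logical).
#' @export
screen_completeness <- function(series, qc = qc_params(),
                                thresholds = threshold_config()) {
  assert_clean_series(series)
  fr <- winter_missing_fractions(series$records, thresholds)
  valid_temp <- fr$frac_missing_tmin <= qc$max_missing_frac_temp &
    fr$frac_missing_tmax <= qc$max_missing_frac_temp
  valid_prcp <- fr$frac_missing_prcp <= qc$max_missing_frac_prcp
  winters <- dplyr::bind_cols(
    tibble::tibble(station_id = rep(series$meta$station_id, nrow(fr))),
    fr,
    tibble::tibble(valid_temp = valid_temp, valid_prcp = valid_prcp)
  )
  n_valid <- sum(valid_temp | valid_prcp)
  list(
    winters = winters,
    n_valid = n_valid,
    station_pass = n_valid >= qc$min_valid_winters
  )
}

#' Gap-fill snow variables
#'
#' Applies three conservative repair rules for the well-known pathologies of
#' archived snow records (chiefly observers leaving snow depth blank instead
#' of writing zero):
#'
#' * (a) missing snowfall is set to 0 on days with zero precipitation, or
#'   with missing precipitation but `tmax` above the rain threshold;
#' * (b) a run of consecutive missing snow-depth days of length at most `k`
#'   whose observed values on both flanks are zero is filled with zeros (the
#'   "unreported zero" repair);
#' * (c) a run of length at most `k` with positive observed depth on both
#'   flanks is filled by linear interpolation in time.
#'
#' Rules (b) and (c) act on maximal gap runs against observed flanking
#' values, so the operation is idempotent; runs longer than `k`, runs with
#' mixed (zero/positive) flanks, and runs touching the record ends are left
#' missing. Every filled value is flagged in `snowfall_filled` /
#' `snow_depth_filled`; observed values are never altered.
#'
#' @param series A `station_series`.
#' @param k Maximum gap length (days) that rules (b) and (c) will fill.
#' @param t_rain Rain threshold (degrees C) for rule (a); the snow model's
#'   `t_rain` by default.
#' @return A new `station_series` whose records gain the two flag columns.
#' @export
gapfill_snow <- function(series, k = 7, t_rain = snow_params()$t_rain) {
  assert_clean_series(series)
  rec <- series$records
  if (!"snowfall_filled" %in% names(rec)) rec$snowfall_filled <- FALSE
  if (!"snow_depth_filled" %in% names(rec)) rec$snow_depth_filled <- FALSE

  # rule a: snowfall
  fill_a <- is.na(rec$snowfall) &
    ((!is.na(rec$prcp) & rec$prcp == 0) |
       (is.na(rec$prcp) & !is.na(rec$tmax) & rec$tmax > t_rain))
  rec$snowfall[fill_a] <- 0
  rec$snowfall_filled <- rec$snowfall_filled | fill_a

  # rules b and c: snow depth, per maximal gap run between observations
  depth <- rec$snow_depth
  obs <- which(!is.na(depth))
  if (length(obs) >= 2L) {
    for (j in seq_len(length(obs) - 1L)) {
      i0 <- obs[j]; i1 <- obs[j + 1L]
      if (i1 - i0 < 2L) next
      gap_days <- as.numeric(rec$date[i1] - rec$date[i0]) - 1
      if (gap_days > k) next
      inner <- (i0 + 1L):(i1 - 1L)
      v0 <- depth[i0]; v1 <- depth[i1]
      if (v0 == 0 && v1 == 0) {
        rec$snow_depth[inner] <- 0
        rec$snow_depth_filled[inner] <- TRUE
      } else if (v0 > 0 && v1 > 0) {
        t0 <- as.numeric(rec$date[i0])
        frac <- (as.numeric(rec$date[inner]) - t0) /
          (as.numeric(rec$date[i1]) - t0)
        rec$snow_depth[inner] <- v0 + frac * (v1 - v0)
        rec$snow_depth_filled[inner] <- TRUE
      }
    }
  }
  station_series(rec, series$meta, check = FALSE)
}
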