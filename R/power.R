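#' Expected frost-day counts under the generator's climate
#'
#' Closed-form expectation of the per-winter frost-day count for a
#' [gen_params()] climate: with daily minimum temperature Gaussian around
#' its seasonal-plus-trend mean with the stationary noise standard
#' deviation, each day's frost probability is `pnorm((0 - mu_d) / sd)` and
#' the expected winter count is the sum over the winter's days. Serial
#' correlation of the noise leaves these expectations unchanged.
#'
#' @param params A [gen_params()] with `noise_sd > 0`.
#' @param thresholds A [threshold_config()] (frost threshold and winter
#'   window).
#' @return A tibble: `winter_year`, `expected_frost` (days).
#' @export
expected_frost_counts <- function(params, thresholds = threshold_config()) {
  stopifnot(inherits(params, "gen_params"), params$noise_sd > 0)
  dates <- seq(as.Date(sprintf("%d-08-01", params$start_year)),
               as.Date(sprintf("%d-07-31", params$start_year + params$n_years)),
               by = "day")
  years_elapsed <- as.numeric(dates - dates[1]) / 365.25
  mu <- seasonal_mean_temp(dates, params) - params$diurnal_range / 2 +
    params$trend_tmin / 10 * years_elapsed
  p_frost <- stats::pnorm((thresholds$t_frost - mu) / params$noise_sd)
  wy <- assign_winter(dates, thresholds)
  keep <- !is.na(wy)
  agg <- rowsum(p_frost[keep], wy[keep])
  tibble::tibble(winter_year = as.integer(rownames(agg)),
                 expected_frost = as.numeric(agg))
}

#' Temperature trend equivalent to a target frost-day trend
#'
#' Inverts the expectation of [expected_frost_counts()]: finds the `tmin`
#' warming trend (degrees C per decade) whose noiseless expected frost-day
#' series has exactly the target Sen slope (days per decade) under the given
#' climate. Used to pose trend-recovery experiments in indicator units
#' ("a forcing equivalent to -1.5 frost days per decade") while driving the
#' generator in temperature units.
#'
#' @param target_slope Target frost-day Sen slope, days per decade
#'   (negative = fewer frost days).
#' @param params A [gen_params()]; its `trend_tmin` is ignored.
#' @param thresholds A [threshold_config()].
#' @param interval Search interval for the temperature trend (degrees C per
#'   decade).
#' @return The equivalent `trend_tmin`, degrees C per decade.
#' @export
frost_slope_to_tmin_trend <- function(target_slope, params,
                                      thresholds = threshold_config(),
                                      interval = c(-3, 3)) {
  slope_of <- function(delta) {
    p <- params
    p$trend_tmin <- delta
    ef <- expected_frost_counts(p, thresholds)
    sen_slope(ef$expected_frost, ef$winter_year)
  }
  stats::uniroot(function(d) slope_of(d) - target_slope,
                 interval = interval, tol = 1e-4)$root
}
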