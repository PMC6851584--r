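#' Mann-Kendall trend test
#'
#' Nonparametric test for monotone trend in an annual series. The statistic
#' is the pairwise sign sum `S = sum_{i<j} sign(x_j - x_i)`; its variance is
#' tie-corrected, `var(S) = [n (n-1) (2n+5) - sum_t t (t-1) (2t+5)] / 18`
#' over groups of `t` tied values; and the normal deviate uses the
#' continuity correction, `z = (S - sign(S)) / sqrt(var(S))` (zero when
#' `S = 0`), with a two-sided normal p value. The Sen slope (median pairwise
#' slope, reported per decade) fills the `sen_slope` column. Missing values
#' are omitted pairwise on the true time axis, so year gaps keep their real
#' spacing.
#'
#' The normal approximation is used throughout (series of interest here have
#' ~100 points); fewer than 4 non-missing values yields an insufficient-data
#' result with `NA` statistics.
#'
#' @param x Numeric series (annual indicator counts); may contain `NA`.
#' @param t Time axis (years); defaults to `seq_along(x)`.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A one-row tibble: `n`, `S`, `var_S`, `z`, `p`, `sen_slope`
#'   (units of `x` per decade), `significant`.
#' @export
#' @examples
#' mann_kendall(1:10)  # S = 45, var_S = 125, z = 44 / sqrt(125)
mann_kendall <- function(x, t = seq_along(x), alpha = 0.05) {
  stopifnot(length(x) == length(t))
  keep <- !is.na(x) & !is.na(t)
  x <- x[keep]; t <- t[keep]
  n <- length(x)
  if (n < 4L) {
    return(tibble::tibble(n = n, S = NA_real_, var_S = NA_real_, z = NA_real_,
                          p = NA_real_, sen_slope = NA_real_,
                          significant = NA))
  }
  d <- outer(x, x, "-")            # d[j, i] = x[j] - x[i]
  S <- sum(sign(d[lower.tri(d)]))  # j > i
  ties <- table(x)
  ties <- ties[ties > 1L]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (S == 0 || var_S == 0) {
    z <- 0
  } else {
    z <- (S - sign(S)) / sqrt(var_S)
  }
  p <- if (var_S == 0) 1 else 2 * stats::pnorm(-abs(z))
  slope <- sen_slope(x, t)
  tibble::tibble(n = n, S = as.numeric(S), var_S = var_S, z = z, p = p,
                 sen_slope = slope, significant = !is.na(p) & p < alpha)
}

#' Sen slope
#'
#' Median of all pairwise slopes `(x_j - x_i) / (t_j - t_i)` over pairs with
#' distinct times, scaled to per-decade units (x 10 for an annual time
#' axis in years).
#'
#' @inheritParams mann_kendall
#' @return Slope per decade (`NA` with fewer than 2 points).
#' @export
#' @examples
#' sen_slope(c(1, 2, 4), t = c(0, 1, 2))  # median(1, 1.5, 2) * 10 = 15
sen_slope <- function(x, t = seq_along(x)) {
  10 * stats::median(pairwise_slopes(x, t))
}

# All pairwise slopes of a series on its time axis (NA pairs and tied times
# dropped); shared by sen_slope and the pooled regional slope.
pairwise_slopes <- function(x, t) {
  keep <- !is.na(x) & !is.na(t)
  x <- x[keep]; t <- t[keep]
  n <- length(x)
  if (n < 2L) return(numeric(0))
  dx <- outer(x, x, "-")[lower.tri(diag(n))]
  dt <- outer(t, t, "-")[lower.tri(diag(n))]
  dx[dt != 0] / dt[dt != 0]
}

#' Autocorrelation screen for an annual series
#'
#' Computes sample autocorrelations of the (mean-removed) series up to
#' `max_lag` (30 years by default — the length of a climate normal) and
#' flags the series when any coefficient leaves the 95% confidence band
#' `+/- z_{0.975} / sqrt(n)`. The flag is advisory: serial correlation is
#' reported alongside the Mann-Kendall result but does not block it, and no
#' prewhitening is applied.
#'
#' @param x Numeric series (may contain `NA`, handled by `na.pass`).
#' @param max_lag Maximum lag in years; truncated to `n - 2` for short
#'   series.
#' @param conf Confidence level of the band.
#' @return A list: `flagged` (logical), `r` (named vector of r_1..r_max_lag),
#'   `bound` (the band half-width).
#' @export
autocorr_screen <- function(x, max_lag = 30, conf = 0.95) {
  n <- sum(!is.na(x))
  max_lag <- min(max_lag, n - 2L)
  if (max_lag < 1L || stats::var(x, na.rm = TRUE) == 0) {
    return(list(flagged = FALSE, r = NULL,
                bound = stats::qnorm(1 - (1 - conf) / 2) / sqrt(max(n, 1))))
  }
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE,
                  na.action = stats::na.pass)
  r <- drop(a$acf)[-1]  # drop lag 0
  names(r) <- paste0("r", seq_along(r))
  bound <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n)
  list(flagged = any(abs(r) > bound, na.rm = TRUE), r = r, bound = bound)
}

#' Regional (site-blocked) Kendall test
#'
#' Extends the Mann-Kendall test across a set of stations by using site as
#' the blocking factor: block statistics and tie-corrected variances are
#' summed (`S_total = sum S_b`, `var_total = sum var_b`, assuming no
#' correlation between blocks), the continuity-corrected deviate gives a
#' two-sided p value, and the regional Sen slope is the median of the
#' pooled within-block pairwise slopes (per decade). Blocks with fewer than
#' 4 usable values are skipped; with a single block the result reduces to
#' [mann_kendall()] on it.
#'
#' @param blocks A data frame with columns `block` (station id), `time`
#'   (year) and `value`; or a named list of `list(values, times)` pairs.
#' @param alpha Two-sided significance level.
#' @return A one-row tibble: `n_blocks`, `S`, `var_S`, `z`, `p`,
#'   `sen_slope`, `significant`.
#' @export
regional_kendall <- function(blocks, alpha = 0.05) {
  if (is.data.frame(blocks)) {
    stopifnot(all(c("block", "time", "value") %in% names(blocks)))
    blocks <- split(blocks[c("value", "time")], blocks$block)
    blocks <- lapply(blocks, function(b) list(values = b$value, times = b$time))
  }
  S_total <- 0
  var_total <- 0
  slopes <- list()
  n_blocks <- 0L
  for (b in blocks) {
    keep <- !is.na(b$values) & !is.na(b$times)
    if (sum(keep) < 4L) next
    mk <- mann_kendall(b$values, b$times, alpha = alpha)
    S_total <- S_total + mk$S
    var_total <- var_total + mk$var_S
    slopes[[length(slopes) + 1L]] <- pairwise_slopes(b$values, b$times)
    n_blocks <- n_blocks + 1L
  }
  if (n_blocks == 0L) {
    return(tibble::tibble(n_blocks = 0L, S = NA_real_, var_S = NA_real_,
                          z = NA_real_, p = NA_real_, sen_slope = NA_real_,
                          significant = NA))
  }
  z <- if (S_total == 0 || var_total == 0) 0 else
    (S_total - sign(S_total)) / sqrt(var_total)
  p <- if (var_total == 0) 1 else 2 * stats::pnorm(-abs(z))
  slope <- 10 * stats::median(unlist(slopes))
  tibble::tibble(n_blocks = n_blocks, S = S_total, var_S = var_total, z = z,
                 p = p, sen_slope = slope,
                 significant = !is.na(p) & p < alpha)
}

#' Assign stations to longitude subregions
#'
#' Partitions the study domain into west / central / east by longitude
#' (negative west). With the default bounds, west is west of 87 W and east
#' is east of 78 W; the boundary meridians themselves belong to the more
#' eastern class (-87 is central, -78 is east), a fixed documented
#' convention.
#'
#' @param longitude Numeric vector, decimal degrees (negative west).
#' @param west_bound,east_bound Boundary meridians (default -87, -78).
#' @return A factor with levels `west`, `central`, `east`.
#' @export
#' @examples
#' assign_subregion(c(-88, -87, -80, -78, -70))
assign_subregion <- function(longitude, west_bound = -87, east_bound = -78) {
  stopifnot(west_bound < east_bound)
  out <- ifelse(longitude < west_bound, "west",
                ifelse(longitude < east_bound, "central", "east"))
  factor(out, levels = c("west", "central", "east"))
}

#' Site-level trend tests for an indicator matrix
#'
#' Runs [mann_kendall()] (with [autocorr_screen()]) on every station x
#' indicator series of a stacked indicator matrix.
#'
#' @param ind_matrix Output of [build_indicator_matrix()], possibly stacked
#'   over stations.
#' @param alpha Significance level.
#' @param max_lag Autocorrelation screen maximum lag.
#' @param indicators Which indicator columns to test (default all 13).
#' @return A tibble: `station_id`, `indicator`, the [mann_kendall()] columns
#'   and `acf_flagged`.
#' @export
site_trends <- function(ind_matrix, alpha = 0.05, max_lag = 30,
                        indicators = indicator_names()) {
  dplyr::bind_rows(lapply(split(ind_matrix, ind_matrix$station_id), function(m) {
    dplyr::bind_rows(lapply(indicators, function(ind) {
      mk <- mann_kendall(m[[ind]], m$winter_year, alpha = alpha)
      scr <- autocorr_screen(m[[ind]], max_lag = max_lag)
      dplyr::bind_cols(
        tibble::tibble(station_id = m$station_id[1], indicator = ind),
        mk, tibble::tibble(acf_flagged = scr$flagged)
      )
    }))
  }))
}

#' Regional trend tests by subregion
#'
#' Runs [regional_kendall()] per indicator for each subregion and for the
#' whole region (`"all"`), blocking on station.
#'
#' @param ind_matrix Stacked indicator matrix.
#' @param stations Station metadata tibble (`station_id`, `longitude`, ...).
#' @param alpha Significance level.
#' @param west_bound,east_bound Subregion boundary meridians.
#' @param indicators Indicator columns to test.
#' @return A tibble: `subregion`, `indicator`, plus [regional_kendall()]
#'   columns.
#' @export
regional_trends <- function(ind_matrix, stations, alpha = 0.05,
                            west_bound = -87, east_bound = -78,
                            indicators = indicator_names()) {
  sub <- assign_subregion(stations$longitude, west_bound, east_bound)
  sub_of <- stats::setNames(as.character(sub), stations$station_id)
  groups <- c(stats::setNames(levels(sub), levels(sub)), all = "all")
  dplyr::bind_rows(lapply(names(groups), function(g) {
    ids <- if (g == "all") stations$station_id else
      stations$station_id[sub_of[stations$station_id] == g]
    m <- ind_matrix[ind_matrix$station_id %in% ids, , drop = FALSE]
    dplyr::bind_rows(lapply(indicators, function(ind) {
      rk <- regional_kendall(data.frame(block = m$station_id,
                                        time = m$winter_year,
                                        value = m[[ind]]), alpha = alpha)
      dplyr::bind_cols(tibble::tibble(subregion = g, indicator = ind), rk)
    }))
  }))
}

#' Subregion trend summary
#'
#' The roll-up reported per indicator and subregion: counts of significantly
#' positive and negative sites, the median and range of Sen slopes over the
#' significant sites only, and the regional slope with its significance
#' (`NA` slope statistics when no site is significant; the regional slope is
#' reported regardless, flagged non-significant when its p exceeds alpha).
#'
#' @param site_tr Output of [site_trends()].
#' @param regional_tr Output of [regional_trends()].
#' @param stations Station metadata tibble.
#' @param west_bound,east_bound Subregion boundary meridians.
#' @return A tibble: `subregion`, `indicator`, `n_sites`, `n_pos`, `n_neg`,
#'   `med_slope`, `min_slope`, `max_slope`, `regional_slope`,
#'   `regional_significant`.
#' @export
summarize_trends <- function(site_tr, regional_tr, stations,
                             west_bound = -87, east_bound = -78) {
  sub <- assign_subregion(stations$longitude, west_bound, east_bound)
  site_tr$subregion <- as.character(sub)[match(site_tr$station_id,
                                               stations$station_id)]
  out <- site_tr |>
    dplyr::group_by(.data$subregion, .data$indicator) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      n_pos = sum(.data$significant & .data$sen_slope > 0, na.rm = TRUE),
      n_neg = sum(.data$significant & .data$sen_slope < 0, na.rm = TRUE),
      med_slope = stats::median(.data$sen_slope[.data$significant %in% TRUE]),
      min_slope = suppressWarnings(min(.data$sen_slope[.data$significant %in% TRUE])),
      max_slope = suppressWarnings(max(.data$sen_slope[.data$significant %in% TRUE])),
      .groups = "drop"
    )
  out$min_slope[!is.finite(out$min_slope)] <- NA_real_
  out$max_slope[!is.finite(out$max_slope)] <- NA_real_
  reg <- regional_tr[, c("subregion", "indicator", "sen_slope", "significant")]
  names(reg)[3:4] <- c("regional_slope", "regional_significant")
  dplyr::left_join(out, reg, by = c("subregion", "indicator"))
}

#' Long-term indicator levels by subregion
#'
#' For each station and indicator, the long-term median annual count over
#' available winters; per subregion, the median and min-max range of those
#' station medians.
#'
#' @inheritParams regional_trends
#' @return A tibble: `subregion`, `indicator`, `n_sites`, `median`, `min`,
#'   `max` (days per winter).
#' @export
summarize_levels <- function(ind_matrix, stations,
                             west_bound = -87, east_bound = -78,
                             indicators = indicator_names()) {
  sub <- assign_subregion(stations$longitude, west_bound, east_bound)
  long <- ind_matrix |>
    tidyr::pivot_longer(dplyr::all_of(indicators), names_to = "indicator",
                        values_to = "count") |>
    dplyr::group_by(.data$station_id, .data$indicator) |>
    dplyr::summarise(station_median = stats::median(.data$count, na.rm = TRUE),
                     .groups = "drop")
  long$subregion <- as.character(sub)[match(long$station_id,
                                            stations$station_id)]
  long |>
    dplyr::group_by(.data$subregion, .data$indicator) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      median = stats::median(.data$station_median, na.rm = TRUE),
      min = suppressWarnings(min(.data$station_median, na.rm = TRUE)),
      max = suppressWarnings(max(.data$station_median, na.rm = TRUE)),
      .groups = "drop"
    )
}
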