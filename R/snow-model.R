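#' Degree-day snow model parameters
#'
#' Parameters of the temperature-index (degree-day) snow water equivalent
#' model. Precipitation phase is partitioned linearly between `t_snow` (all
#' snow at or below) and `t_rain` (all rain at or above); melt is
#' proportional to degrees above `t_melt` with factor `ddf`; a small liquid
#' store of capacity `retain_frac * swe` holds rain and meltwater in the
#' pack, refreezing at `refreeze_factor` per degree below `t_melt`.
#'
#' Defaults are central literature values for daily temperature-index models
#' in seasonal-snow climates; all are exposed for calibration (see
#' [calibrate_snow_params()]).
#'
#' @param t_snow Degrees C at/below which precipitation is all snow.
#' @param t_rain Degrees C at/above which precipitation is all rain
#'   (`t_snow <= t_rain`).
#' @param t_melt Melt base temperature, degrees C.
#' @param ddf Degree-day melt factor, mm per degree C per day (> 0).
#' @param retain_frac Fraction of SWE that can be held as liquid in the pack,
#'   in \[0, 1\].
#' @param refreeze_factor Refreeze rate, mm per degree C per day (>= 0).
#' @return A list of class `snow_params`.
#' @export
snow_params <- function(t_snow = 0, t_rain = 2, t_melt = 0, ddf = 2.5,
                        retain_frac = 0.05, refreeze_factor = 1.0) {
  stopifnot(t_snow <= t_rain, ddf > 0, retain_frac >= 0, retain_frac <= 1,
            refreeze_factor >= 0)
  structure(
    list(t_snow = t_snow, t_rain = t_rain, t_melt = t_melt, ddf = ddf,
         retain_frac = retain_frac, refreeze_factor = refreeze_factor),
    class = "snow_params"
  )
}

#' Partition daily precipitation into rain and snow
#'
#' Below `t_snow` all precipitation falls as snow, above `t_rain` all as
#' rain, and in between the rain fraction rises linearly; rain and snow sum
#' to the input exactly. With `t_snow == t_rain` the split is a step: rain at
#' or above the threshold. A missing mean temperature leaves both components
#' undefined.
#'
#' @param tavg Daily mean temperature, degrees C (vectorised, may be `NA`).
#' @param prcp Daily precipitation, mm liquid equivalent (>= 0).
#' @param params A [snow_params()].
#' @return A tibble with numeric columns `rain` and `snow` (mm).
#' @export
#' @examples
#' partition_precipitation(tavg = 1, prcp = 10)  # 5 mm rain, 5 mm snow
partition_precipitation <- function(tavg, prcp, params = snow_params()) {
  stopifnot(all(prcp >= 0, na.rm = TRUE))
  n <- max(length(tavg), length(prcp))
  tavg <- rep_len(as.numeric(tavg), n)
  prcp <- rep_len(as.numeric(prcp), n)
  if (params$t_rain > params$t_snow) {
    frac_rain <- (tavg - params$t_snow) / (params$t_rain - params$t_snow)
    frac_rain <- pmin(1, pmax(0, frac_rain))
  } else {
    frac_rain <- as.numeric(tavg >= params$t_rain)
  }
  rain <- frac_rain * prcp
  tibble::tibble(rain = rain, snow = prcp - rain)
}

#' Advance the snowpack by one day
#'
#' One explicit daily step of the degree-day model: new snow accumulates,
#' melt (capped at the available SWE) and rain feed the liquid store up to
#' its capacity with the excess leaving as runoff, and liquid refreezes into
#' the pack on cold days. Mass is conserved exactly: the change in
#' `swe + liquid_store` equals `snow + rain - runoff`. A day with missing
#' temperature or precipitation carries the state forward unchanged and is
#' flagged undefined.
#'
#' @param state A list with numeric `swe` and `liquid_store` (mm, >= 0), e.g.
#'   `swe_state()`.
#' @param day A list or one-row data frame with `tmin`, `tmax`, `prcp`.
#' @param params A [snow_params()].
#' @return A list: `state` (updated), `fluxes` (list of `rain`, `snow`,
#'   `melt`, `refreeze`, `runoff` in mm) and `defined` (logical).
#' @export
step_swe <- function(state, day, params = snow_params()) {
  tavg <- (day$tmin + day$tmax) / 2
  prcp <- day$prcp
  if (is.na(tavg) || is.na(prcp)) {
    return(list(state = state,
                fluxes = list(rain = NA_real_, snow = NA_real_, melt = NA_real_,
                              refreeze = NA_real_, runoff = NA_real_),
                defined = FALSE))
  }
  part <- partition_precipitation(tavg, prcp, params)
  swe <- state$swe + part$snow
  melt <- min(swe, params$ddf * max(0, tavg - params$t_melt))
  swe <- swe - melt
  liquid_in <- state$liquid_store + melt + part$rain
  capacity <- params$retain_frac * swe
  liquid <- min(liquid_in, capacity)
  runoff <- liquid_in - liquid
  refreeze <- min(liquid, params$refreeze_factor * max(0, params$t_melt - tavg))
  liquid <- liquid - refreeze
  swe <- swe + refreeze
  list(
    state = list(swe = swe, liquid_store = liquid),
    fluxes = list(rain = part$rain, snow = part$snow, melt = melt,
                  refreeze = refreeze, runoff = runoff),
    defined = TRUE
  )
}

#' Empty snowpack state
#' @param swe,liquid_store Initial stores in mm (default empty).
#' @return A list with `swe` and `liquid_store`.
#' @export
swe_state <- function(swe = 0, liquid_store = 0) {
  stopifnot(swe >= 0, liquid_store >= 0)
  list(swe = swe, liquid_store = liquid_store)
}

#' Simulate daily SWE over a station record
#'
#' Runs [step_swe()] sequentially over the whole record with daily mean
#' temperature `(tmin + tmax) / 2`. The pack is initialised empty and reset
#' to empty at the start of each hydrological year (1 August), so winters
#' never inherit a phantom pack across snow-free summers and results do not
#' depend on where the record starts. Days with missing forcing carry the
#' state forward and are flagged undefined (their `swe` is reported `NA`).
#' The daily loop runs in compiled code; the result is deterministic.
#'
#' @param series A `station_series`.
#' @param params A [snow_params()].
#' @param init Optional [swe_state()] used before the first hydrological-year
#'   reset.
#' @return A tibble: `date`, `swe` (mm, `NA` when undefined), `modeled`
#'   (logical), and daily fluxes `rain`, `snow`, `melt`, `refreeze`,
#'   `runoff` (mm).
#' @export
simulate_swe <- function(series, params = snow_params(), init = swe_state()) {
  assert_clean_series(series)
  rec <- series$records
  tavg <- (rec$tmin + rec$tmax) / 2
  dp <- date_parts(rec$date)
  hydro_year <- dp$year + as.integer(dp$month >= 8L)
  reset <- c(TRUE, diff(hydro_year) != 0L)
  reset[1] <- FALSE  # first day uses `init`
  sim <- swe_run_cpp(tavg, rec$prcp, reset,
                     params$t_snow, params$t_rain, params$t_melt, params$ddf,
                     params$retain_frac, params$refreeze_factor,
                     init$swe, init$liquid_store)
  swe <- sim$swe
  swe[!sim$defined] <- NA_real_
  tibble::tibble(
    date = rec$date, swe = swe, modeled = sim$defined,
    rain = sim$rain, snow = sim$snow, melt = sim$melt,
    refreeze = sim$refreeze, runoff = sim$runoff
  )
}

#' Calibrate snow parameters by grid search
#'
#' Exhaustive search over a grid of candidate parameter sets, scoring each by
#' the day-wise agreement of snow presence between observed snow depth
#' (`snow_depth > 0`) and modeled SWE (`swe > 0`), over days where both are
#' defined. Ties at the maximum agreement are broken toward the default
#' parameter set ([snow_params()]): among tied candidates the one closest to
#' the defaults (smallest scaled absolute difference) is returned.
#'
#' @param series A `station_series` whose records include observed (possibly
#'   gap-filled) `snow_depth`.
#' @param grid A data frame of candidate parameter values; columns are any
#'   subset of the [snow_params()] fields, absent fields take defaults.
#' @return A list: `params` (the winning [snow_params()]), `agreement`
#'   (fraction of days agreeing), `n_days` (days scored) and `scores`
#'   (the grid with an `agreement` column).
#' @export
calibrate_snow_params <- function(series, grid) {
  assert_clean_series(series)
  grid <- as.data.frame(grid)
  stopifnot(nrow(grid) >= 1L)
  defaults <- snow_params()
  fields <- names(defaults)
  unknown <- setdiff(names(grid), fields)
  if (length(unknown) > 0L) stop("unknown snow parameter(s): ", paste(unknown, collapse = ", "))
  obs <- series$records$snow_depth

  candidate <- function(i) {
    args <- as.list(defaults)
    for (f in intersect(names(grid), fields)) args[[f]] <- grid[[f]][i]
    do.call(snow_params, args)
  }
  scores <- numeric(nrow(grid))
  n_used <- 0L
  for (i in seq_len(nrow(grid))) {
    p <- candidate(i)
    sim <- simulate_swe(series, p)
    use <- !is.na(obs) & sim$modeled
    if (!any(use)) {
      scores[i] <- NA_real_
      next
    }
    n_used <- sum(use)
    scores[i] <- mean((obs[use] > 0) == (sim$swe[use] > 0))
  }
  if (all(is.na(scores))) {
    stop("no usable observed snow-depth days; cannot calibrate (defaults recommended)")
  }
  best <- max(scores, na.rm = TRUE)
  tied <- which(!is.na(scores) & scores == best)
  if (length(tied) > 1L) {
    dist_to_default <- vapply(tied, function(i) {
      p <- candidate(i)
      sum(vapply(fields, function(f) {
        abs(p[[f]] - defaults[[f]]) / max(abs(defaults[[f]]), 1)
      }, numeric(1)))
    }, numeric(1))
    winner <- tied[which.min(dist_to_default)]
  } else {
    winner <- tied
  }
  grid_scores <- tibble::as_tibble(grid)
  grid_scores$agreement <- scores
  list(params = candidate(winner), agreement = best, n_days = n_used,
       scores = grid_scores)
}
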