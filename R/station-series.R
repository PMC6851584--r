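#' Station metadata
#'
#' Create the metadata record for a weather station: an opaque identifier plus
#' geographic coordinates (decimal degrees, longitude negative west of
#' Greenwich).
#'
#' @param station_id Character scalar, unique within a run.
#' @param latitude Decimal degrees, in \[-90, 90\].
#' @param longitude Decimal degrees, in \[-180, 180\]; negative = west.
#' @param name Optional human-readable name; defaults to `station_id`.
#'
#' @return A one-row tibble of class `station_meta`.
#' @export
#' @examples
#' station_meta("XYZ001", 45.2, -71.5)
station_meta <- function(station_id, latitude, longitude, name = station_id) {
  stopifnot(
    is.character(station_id), length(station_id) == 1L, nzchar(station_id),
    is.numeric(latitude), length(latitude) == 1L,
    latitude >= -90, latitude <= 90,
    is.numeric(longitude), length(longitude) == 1L,
    longitude >= -180, longitude <= 180
  )
  out <- tibble::tibble(
    station_id = station_id,
    latitude = as.numeric(latitude),
    longitude = as.numeric(longitude),
    name = as.character(name)
  )
  class(out) <- c("station_meta", class(out))
  out
}

#' Daily station weather series
#'
#' Bundle a station's daily records with its metadata. Records hold one row
#' per calendar date with the five daily variables in internal units:
#' temperatures in degrees Celsius, precipitation in mm liquid equivalent,
#' snowfall and snow depth in mm solid. Missing observations are `NA`.
#'
#' Construction enforces the record invariants: dates are `Date`s in strictly
#' increasing order (calendar gaps are allowed, duplicates are not), `tmin <=
#' tmax` whenever both are present, and precipitation, snowfall and snow depth
#' are non-negative when present.
#'
#' @param records A data frame with columns `date`, `tmin`, `tmax`, `prcp`,
#'   `snowfall`, `snow_depth`. Extra columns (e.g. imputation flags) are kept.
#' @param meta A [station_meta()] row.
#' @param check If `FALSE`, skip invariant checks (used internally after
#'   operations that preserve them).
#'
#' @return A list of class `station_series` with elements `meta` and
#'   `records` (a tibble).
#' @export
station_series <- function(records, meta, check = TRUE) {
  stopifnot(inherits(meta, "station_meta"))
  records <- tibble::as_tibble(records)
  required <- c("date", "tmin", "tmax", "prcp", "snowfall", "snow_depth")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!inherits(records$date, "Date")) {
    records$date <- as.Date(records$date)
  }
  for (v in setdiff(required, "date")) records[[v]] <- as.numeric(records[[v]])
  if (check) {
    if (anyNA(records$date)) stop("records contain unparseable dates")
    if (is.unsorted(records$date, strictly = FALSE)) {
      stop("record dates must be non-decreasing")
    }
    if (anyDuplicated(records$date)) {
      warning("duplicate dates present; downstream operations will refuse this series")
    }
    both <- !is.na(records$tmin) & !is.na(records$tmax)
    if (any(records$tmin[both] > records$tmax[both])) {
      stop("tmin > tmax on ", sum(records$tmin[both] > records$tmax[both], na.rm = TRUE),
           " row(s); quarantine these before constructing the series")
    }
    for (v in c("prcp", "snowfall", "snow_depth")) {
      if (any(records[[v]] < 0, na.rm = TRUE)) {
        stop("negative values in ", v)
      }
    }
  }
  structure(list(meta = meta, records = records), class = "station_series")
}

#' @export
print.station_series <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<station_series> %s (%s) lat %.3f lon %.3f\n  %d daily records, %s to %s\n",
    m$station_id, m$name, m$latitude, m$longitude,
    nrow(x$records),
    format(min(x$records$date)), format(max(x$records$date))
  ))
  invisible(x)
}

#' @export
format.station_series <- function(x, ...) {
  sprintf("<station_series %s, %d records>", x$meta$station_id, nrow(x$records))
}

# Refuse series whose date axis is unusable for sequential computation.
assert_clean_series <- function(series) {
  stopifnot(inherits(series, "station_series"))
  d <- series$records$date
  if (anyNA(d)) stop("series has records with missing dates")
  if (anyDuplicated(d)) {
    stop("series for station ", series$meta$station_id,
         " has duplicate dates; refusing (conflicting duplicate reports cannot be resolved)")
  }
  if (is.unsorted(d, strictly = TRUE)) stop("series dates are not strictly increasing")
  invisible(series)
}
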