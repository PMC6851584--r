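#' Describe the on-disk layout of a daily station CSV
#'
#' A dialect names the column mapping, the unit scale of each numeric column,
#' and the missing-value sentinel, so that files from different archives can
#' be normalised to internal units (degrees C, mm) at read time.
#'
#' @param col_map Named character vector mapping internal names (`date`,
#'   `tmin`, `tmax`, `prcp`, `snowfall`, `snow_depth`) to file column names.
#' @param scale Either the string `"plain"` (values already in degrees C / mm),
#'   the string `"tenths"` (values in tenths, as in raw GHCN-Daily element
#'   files), or a named numeric vector of multipliers applied after sentinel
#'   substitution.
#' @param sentinel Numeric missing-value code in the file (compared before
#'   scaling). Default -9999.
#' @param date_format `strptime` format of the date column.
#'
#' @return A list of class `station_dialect`.
#' @export
#' @examples
#' station_dialect(scale = "tenths")
station_dialect <- function(col_map = NULL,
                            scale = "plain",
                            sentinel = -9999,
                            date_format = "%Y-%m-%d") {
  vars <- c("date", "tmin", "tmax", "prcp", "snowfall", "snow_depth")
  if (is.null(col_map)) col_map <- stats::setNames(vars, vars)
  stopifnot(all(vars %in% names(col_map)))
  num_vars <- setdiff(vars, "date")
  if (is.character(scale) && length(scale) == 1L) {
    scale <- switch(scale,
      plain = stats::setNames(rep(1, 5L), num_vars),
      tenths = stats::setNames(rep(0.1, 5L), num_vars),
      stop("unknown scale shorthand: ", scale)
    )
  }
  stopifnot(is.numeric(scale), all(num_vars %in% names(scale)))
  structure(
    list(col_map = col_map[vars], scale = scale[num_vars],
         sentinel = sentinel, date_format = date_format),
    class = "station_dialect"
  )
}

#' Read one station's daily weather file
#'
#' Reads a per-station CSV in the layout described by `dialect`, substitutes
#' the missing-value sentinel with `NA`, converts to internal units (degrees
#' C, mm), and returns a validated [station_series()]. Rows whose date cannot
#' be parsed are rejected with a warning. Rows with `tmin > tmax` are
#' quarantined: both temperatures are set missing and a warning reports the
#' affected dates (the other variables on those rows are kept).
#'
#' @param path Path to the CSV file.
#' @param meta A [station_meta()] row for this station.
#' @param dialect A [station_dialect()].
#'
#' @return A `station_series`. The dates of quarantined rows are attached as
#'   attribute `"quarantined"`.
#' @export
read_station_daily <- function(path, meta, dialect = station_dialect()) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  cm <- dialect$col_map
  missing_cols <- setdiff(unname(cm), names(raw))
  if (length(missing_cols) > 0L) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  dates <- as.Date(raw[[cm[["date"]]]], format = dialect$date_format)
  bad_dates <- is.na(dates) & !is.na(raw[[cm[["date"]]]]) | is.na(raw[[cm[["date"]]]])
  if (any(bad_dates)) {
    warning(sum(bad_dates), " row(s) with unparseable dates rejected")
  }
  rec <- tibble::tibble(date = dates[!bad_dates])
  for (v in c("tmin", "tmax", "prcp", "snowfall", "snow_depth")) {
    x <- suppressWarnings(as.numeric(raw[[cm[[v]]]][!bad_dates]))
    x[!is.na(x) & x == dialect$sentinel] <- NA_real_
    rec[[v]] <- x * dialect$scale[[v]]
  }
  both <- !is.na(rec$tmin) & !is.na(rec$tmax)
  swapped <- both & rec$tmin > rec$tmax
  quarantined <- rec$date[swapped]
  if (any(swapped)) {
    warning(sum(swapped), " row(s) with tmin > tmax quarantined (temperatures set missing): ",
            paste(format(utils::head(quarantined, 5L)), collapse = ", "),
            if (sum(swapped) > 5L) ", ..." else "")
    rec$tmin[swapped] <- NA_real_
    rec$tmax[swapped] <- NA_real_
  }
  out <- station_series(rec, meta)
  attr(out, "quarantined") <- quarantined
  out
}

#' Write a station series in a given dialect
#'
#' Inverse of [read_station_daily()]: converts internal units back to the
#' dialect's units, replaces `NA` with the sentinel, and writes a CSV.
#' Numeric values are written at the dialect's resolution (0.1 in internal
#' units), so a write/read round trip reproduces values to 0.1.
#'
#' @param series A `station_series`.
#' @param path Output file path.
#' @param dialect A [station_dialect()].
#' @return `path`, invisibly.
#' @export
write_station_daily <- function(series, path, dialect = station_dialect()) {
  stopifnot(inherits(series, "station_series"))
  rec <- series$records
  out <- stats::setNames(
    list(format(rec$date, dialect$date_format)),
    dialect$col_map[["date"]]
  )
  for (v in c("tmin", "tmax", "prcp", "snowfall", "snow_depth")) {
    x <- rec[[v]] / dialect$scale[[v]]
    # one decimal at internal 0.1 resolution, scaled by the dialect
    digits <- max(0L, 1L + round(log10(dialect$scale[[v]])))
    x <- round(x, digits)
    x[is.na(x)] <- dialect$sentinel
    out[[dialect$col_map[[v]]]] <- x
  }
  readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Read a station metadata table
#'
#' @param path CSV with columns `station_id`, `latitude`, `longitude` and
#'   optionally `name`.
#' @return A tibble, one row per station; ids must be unique and coordinates
#'   in range.
#' @export
read_station_meta <- function(path) {
  stopifnot(file.exists(path))
  m <- readr::read_csv(path, col_types = readr::cols(
    station_id = readr::col_character(),
    latitude = readr::col_double(),
    longitude = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  if (!all(c("station_id", "latitude", "longitude") %in% names(m))) {
    stop("station metadata must have columns station_id, latitude, longitude")
  }
  if (!"name" %in% names(m)) m$name <- m$station_id
  if (anyDuplicated(m$station_id)) stop("duplicate station_id in metadata")
  if (any(abs(m$latitude) > 90, na.rm = TRUE) || any(abs(m$longitude) > 180, na.rm = TRUE)) {
    stop("station coordinates out of range")
  }
  m
}

#' Validation report for a station series
#'
#' A pure reporting pass over a series: per-winter missing fractions for each
#' variable (days absent from the record count as missing within the 1 Nov -
#' 31 May window), plus any duplicate or out-of-order dates. The series is
#' not modified; duplicates are reported, never dropped.
#'
#' @param series A `station_series`.
#' @param thresholds A [threshold_config()]; only its winter window is used.
#' @return A list with elements `winters` (tibble: `winter_year`, `n_days`,
#'   `frac_missing_<var>` for the five variables), `duplicate_dates` (Date
#'   vector) and `unordered` (logical).
#' @export
validate_series <- function(series, thresholds = threshold_config()) {
  stopifnot(inherits(series, "station_series"))
  rec <- series$records
  dup <- rec$date[duplicated(rec$date)]
  unordered <- is.unsorted(rec$date, strictly = FALSE)
  winters <- winter_missing_fractions(rec, thresholds)
  list(winters = winters, duplicate_dates = unique(dup), unordered = unordered)
}

# Per-winter missing fraction of each variable over the full winter window;
# calendar days absent from the record count as missing.
winter_missing_fractions <- function(rec, thresholds = threshold_config()) {
  wy <- assign_winter(rec$date, thresholds)
  vars <- c("tmin", "tmax", "prcp", "snowfall", "snow_depth")
  years <- sort(unique(wy[!is.na(wy)]))
  if (length(years) == 0L) {
    out <- tibble::tibble(winter_year = integer(), n_days = integer())
    for (v in vars) out[[paste0("frac_missing_", v)]] <- numeric()
    return(out)
  }
  in_winter <- !is.na(wy)
  swy <- wy[in_winter]
  present <- vapply(vars, function(v) !is.na(rec[[v]][in_winter]),
                    logical(sum(in_winter)))
  if (sum(in_winter) == 1L) present <- matrix(present, nrow = 1L, dimnames = list(NULL, vars))
  tally <- rowsum(present * 1L, as.character(swy))
  tally <- tally[match(as.character(years), rownames(tally)), , drop = FALSE]
  n_days <- winter_length(years, thresholds)
  out <- tibble::tibble(winter_year = years, n_days = n_days)
  for (v in vars) out[[paste0("frac_missing_", v)]] <- 1 - tally[, v] / n_days
  out
}
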