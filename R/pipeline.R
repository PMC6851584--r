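#' Pipeline configuration
#'
#' One object holding every tunable of the full analysis: input mode (read
#' station files or synthesize them), the station roster, QC, snow-model and
#' indicator-threshold parameters, the significance level, the subregion
#' boundary meridians and the global seed. Every stochastic choice in a run
#' is fixed by `seed`; synthetic stations draw per-station substreams keyed
#' by station id, so adding a station never perturbs the others.
#'
#' @param mode `"synthesize"` or `"read"`.
#' @param stations For `synthesize`: a tibble with `station_id`, `latitude`,
#'   `longitude` and optionally columns overriding [gen_params()] fields
#'   (e.g. `trend_tmin`). For `read`: a tibble with `station_id`, `latitude`,
#'   `longitude`, `path`.
#' @param gen Baseline [gen_params()] for synthetic stations (per-station
#'   columns override its fields; seeds are derived from `seed`).
#' @param dialect A [station_dialect()] for `read` mode.
#' @param qc A [qc_params()].
#' @param snow A [snow_params()].
#' @param thresholds A [threshold_config()].
#' @param alpha Significance level for all trend tests.
#' @param west_bound,east_bound Subregion boundary meridians.
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthesize", "read"), stations,
                            gen = gen_params(), dialect = station_dialect(),
                            qc = qc_params(), snow = snow_params(),
                            thresholds = threshold_config(), alpha = 0.05,
                            west_bound = -87, east_bound = -78, seed = 1L) {
  mode <- match.arg(mode)
  stations <- tibble::as_tibble(stations)
  stopifnot(all(c("station_id", "latitude", "longitude") %in% names(stations)))
  if (anyDuplicated(stations$station_id)) stop("duplicate station_id")
  if (mode == "read" && !"path" %in% names(stations)) {
    stop("read mode needs a 'path' column in stations")
  }
  structure(
    list(mode = mode, stations = stations, gen = gen, dialect = dialect,
         qc = qc, snow = snow, thresholds = thresholds, alpha = alpha,
         west_bound = west_bound, east_bound = east_bound,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML document onto [pipeline_config()]: top-level keys `mode`,
#' `alpha`, `west_bound`, `east_bound`, `seed`; mapping keys `gen`, `qc`,
#' `snow`, `thresholds`, `dialect` holding the corresponding constructor
#' arguments; and `stations`, a list of per-station mappings.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  stations <- dplyr::bind_rows(lapply(y$stations, tibble::as_tibble))
  args <- list(mode = y$mode %||% "synthesize", stations = stations)
  if (!is.null(y$gen)) args$gen <- do.call(gen_params, y$gen)
  if (!is.null(y$qc)) args$qc <- do.call(qc_params, y$qc)
  if (!is.null(y$snow)) args$snow <- do.call(snow_params, y$snow)
  if (!is.null(y$thresholds)) args$thresholds <- do.call(threshold_config, y$thresholds)
  if (!is.null(y$dialect)) args$dialect <- do.call(station_dialect, y$dialect)
  for (k in c("alpha", "west_bound", "east_bound", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build one station's series according to the config.
load_station <- function(config, i) {
  st <- config$stations[i, ]
  meta <- station_meta(st$station_id, st$latitude, st$longitude,
                       if ("name" %in% names(st)) st$name else st$station_id)
  if (config$mode == "read") {
    return(read_station_daily(st$path, meta, config$dialect))
  }
  args <- as.list(config$gen)
  class(args) <- NULL
  overrides <- intersect(names(st), setdiff(names(args), "seed"))
  for (f in overrides) if (!is.na(st[[f]])) args[[f]] <- st[[f]]
  args$seed <- station_seed(config$seed, st$station_id)
  generate_daily_series(do.call(gen_params, args), meta = meta,
                        snow = config$snow)
}

#' Run the full indicator-trend pipeline
#'
#' Executes every stage in order for each station — load or generate the
#' daily series, screen completeness, gap-fill snow, simulate SWE, build the
#' winter indicator matrix — then stacks stations and computes site trends,
#' regional (site-blocked) trends per subregion, and the trend and level
#' summaries. Deterministic given the config (including its seed).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every table is written as
#'   CSV together with a JSON run manifest (config hash, package version,
#'   per-stage record counts).
#' @param apply_qc If `TRUE` (default) stations failing the completeness
#'   screen are dropped and winter validity masks the indicator matrix.
#' @return A list: `series` (per-station `station_series`), `qc` (per-winter
#'   validity), `stations_kept`, `indicator_matrix`, `site_trends`,
#'   `regional_trends`, `trend_summary`, `level_summary`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, apply_qc = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  n_st <- nrow(config$stations)
  series <- vector("list", n_st)
  qc_rows <- vector("list", n_st)
  matrices <- vector("list", n_st)
  kept <- logical(n_st)
  for (i in seq_len(n_st)) {
    s <- load_station(config, i)
    assert_clean_series(s)
    scr <- screen_completeness(s, config$qc, config$thresholds)
    s <- gapfill_snow(s, t_rain = config$snow$t_rain)
    kept[i] <- !apply_qc || scr$station_pass
    series[[i]] <- s
    qc_rows[[i]] <- scr$winters
    if (!kept[i]) next
    validity <- if (apply_qc) scr$winters else NULL
    matrices[[i]] <- build_indicator_matrix(
      s, swe = simulate_swe(s, config$snow), validity = validity,
      thresholds = config$thresholds, snow = config$snow
    )
  }
  names(series) <- config$stations$station_id
  ind_matrix <- dplyr::bind_rows(matrices)
  stations_kept <- config$stations[kept, , drop = FALSE]
  if (nrow(ind_matrix) == 0L) stop("no station passed QC; nothing to analyse")

  site_tr <- site_trends(ind_matrix, alpha = config$alpha)
  reg_tr <- regional_trends(ind_matrix, stations_kept, alpha = config$alpha,
                            west_bound = config$west_bound,
                            east_bound = config$east_bound)
  tr_sum <- summarize_trends(site_tr, reg_tr, stations_kept,
                             west_bound = config$west_bound,
                             east_bound = config$east_bound)
  lv_sum <- summarize_levels(ind_matrix, stations_kept,
                             west_bound = config$west_bound,
                             east_bound = config$east_bound)

  manifest <- list(
    package_version = as.character(utils::packageVersion("wintertrends")),
    config_hash = rlang::hash(config),
    seed = config$seed,
    mode = config$mode,
    n_stations = n_st,
    n_stations_kept = sum(kept),
    n_station_winters = nrow(ind_matrix),
    n_site_tests = nrow(site_tr),
    n_regional_tests = nrow(reg_tr)
  )
  out <- list(series = series,
              qc = dplyr::bind_rows(qc_rows),
              stations_kept = stations_kept,
              indicator_matrix = ind_matrix,
              site_trends = site_tr, regional_trends = reg_tr,
              trend_summary = tr_sum, level_summary = lv_sum,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out$qc, file.path(out_dir, "qc_report.csv"))
    readr::write_csv(ind_matrix, file.path(out_dir, "indicator_matrix.csv"))
    readr::write_csv(site_tr, file.path(out_dir, "site_trends.csv"))
    readr::write_csv(reg_tr, file.path(out_dir, "regional_trends.csv"))
    readr::write_csv(tr_sum, file.path(out_dir, "trend_summary.csv"))
    readr::write_csv(lv_sum, file.path(out_dir, "level_summary.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}
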