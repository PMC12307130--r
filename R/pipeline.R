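#' Pipeline configuration
#'
#' Reads the single YAML configuration file driving the command-line
#' pipeline. Per-stage blocks (`radar`, `quantification`, `clutter`,
#' `tracking`, `summary`) override built-in defaults; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @return List of class `pipeline_config` with the stage blocks
#'   materialised (`radar` as [radar_config()], `quantification` as
#'   [quant_config()], plus `clutter`, `tracking`, `summary` lists) and a
#'   `hash` of the canonical configuration.
#' @export
pipeline_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known_blocks <- c("radar", "quantification", "clutter", "tracking",
                    "summary")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown)) {
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  take <- function(block, defaults) {
    vals <- raw[[block]]
    bad <- setdiff(names(vals), names(defaults))
    if (length(bad)) {
      stop("unknown key(s) in block '", block, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    utils::modifyList(defaults, vals %||% list())
  }
  radar_args <- take("radar", formals_defaults(radar_config))
  quant_args <- take("quantification", formals_defaults(quant_config))
  clutter <- take("clutter", list(quantile = 0.02, max_range = 27.5,
                                  statistic = "eta"))
  tracking <- take("tracking", list(metric = "area"))
  summary <- take("summary", list(bandwidth = 10, min_days_per_year = 30,
                                  min_scans = 6,
                                  include_clutter_mixed = TRUE))
  cfg <- list(radar = do.call(radar_config, radar_args),
              quantification = do.call(quant_config, quant_args),
              clutter = clutter, tracking = tracking, summary = summary)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

formals_defaults <- function(fn) {
  f <- formals(fn)
  lapply(f, eval, envir = baseenv())
}

# md5 of the canonical JSON form of the config (provenance stamp)
config_hash <- function(cfg) {
  plain <- rapply(unclass(cfg[setdiff(names(cfg), "hash")]),
                  function(x) x, how = "replace")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S", tz = "UTC"),
                  paste0(...)))
}

write_run_manifest <- function(out_dir, cfg, command, seed = NULL) {
  jsonlite::write_json(
    list(command = command, config_hash = cfg$hash, seed = seed,
         package_version = as.character(utils::packageVersion("roostradar"))),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
}

#' Run a pipeline stage
#'
#' Thin programmatic equivalent of the `roostradar` command-line script.
#' Subcommands: `simulate` (synthetic series + annotations), `build-mask`,
#' `quantify`, `track`, `summarize`, `cluster`, `compare`. Each reads and
#' writes the documented plain-text artifacts under `out_dir` and records
#' a run manifest with the configuration hash.
#'
#' @param command Subcommand name.
#' @param config A [pipeline_config()].
#' @param paths Named list of input/output locations; all commands need
#'   `out_dir`, the rest is per command: `simulate` (`days`, optional
#'   `seed`), `build-mask`/`quantify` (`series`), `quantify`
#'   (`annotations`, optional `masks`), `track` (`detections`),
#'   `summarize` (`series`, `tracks`), `cluster` (`tracks`), `compare`
#'   (`summary_a`, `summary_b`, `area_a`, `area_b`).
#' @return The primary artifact of the stage, invisibly.
#' @export
rr_run <- function(command, config = pipeline_config(), paths = list()) {
  out_dir <- paths$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  qc <- config$quantification
  result <- switch(
    command,
    "simulate" = {
      seed <- as.integer(paths$seed %||% 1L)
      days <- as.Date(paths$days %||% Sys.Date())
      scene <- demo_scene(config$radar, days = days, seed = seed, qc = qc)
      write_series(scene$series, file.path(out_dir, "series"))
      write_annotations(scene$annotations,
                        file.path(out_dir, "annotations.csv"))
      log_msg("INFO", "simulated ", length(scene$series$volumes),
              " volumes over ", length(days), " day(s)")
      scene
    },
    "build-mask" = {
      series <- read_series(paths$series)
      masks <- build_masks(series, quantile = config$clutter$quantile,
                           max_range = config$clutter$max_range,
                           statistic = config$clutter$statistic)
      write_masks(masks, file.path(out_dir, "masks"))
      log_msg("INFO", "built ", length(masks), " mask(s)")
      masks
    },
    "quantify" = {
      series <- read_series(paths$series)
      ann <- read_annotations(paths$annotations)
      masks <- if (!is.null(paths$masks)) read_masks(paths$masks)
      det <- quantify_boxes(series, ann, qc, masks)
      data.table::fwrite(det, file.path(out_dir, "detections.csv"))
      log_msg("INFO", "quantified ", nrow(det), " detection(s)")
      det
    },
    "track" = {
      det <- as.data.frame(data.table::fread(paths$detections))
      det$timestamp <- as.POSIXct(det$timestamp, tz = "UTC")
      linked <- track_series(det, metric = config$tracking$metric)
      tracks <- track_table(linked)
      data.table::fwrite(tracks, file.path(out_dir, "tracks.csv"))
      log_msg("INFO", nrow(tracks), " track(s)")
      tracks
    },
    "summarize" = {
      series <- read_series(paths$series)
      tracks <- read_tracks(paths$tracks)
      summ <- summarize_days(series, tracks,
                             min_scans = config$summary$min_scans,
                             include_clutter_mixed =
                               config$summary$include_clutter_mixed)
      data.table::fwrite(summ, file.path(out_dir, "daily_summary.csv"))
      data.table::fwrite(presence_reconciliation(summ),
                         file.path(out_dir, "presence_reconciliation.csv"))
      log_msg("INFO", sum(summ$status == "sampled"), " sampled day(s)")
      summ
    },
    "cluster" = {
      tracks <- read_tracks(paths$tracks)
      cl <- cluster_roosts(tracks, bandwidth = config$summary$bandwidth)
      flagged <- stable_vs_satellite(cl, config$summary$min_days_per_year)
      data.table::fwrite(flagged, file.path(out_dir, "clusters.csv"))
      log_msg("INFO", nrow(flagged), " cluster(s)")
      cl
    },
    "compare" = {
      sa <- read_summary(paths$summary_a)
      sb <- read_summary(paths$summary_b)
      cmp <- compare_regions(sa, sb, as.numeric(paths$area_a),
                             as.numeric(paths$area_b))
      jsonlite::write_json(
        list(area_ratio = cmp$area_ratio, by_year = cmp$by_year),
        file.path(out_dir, "comparison.json"), auto_unbox = TRUE,
        digits = NA, dataframe = "rows")
      cmp
    },
    stop("unknown command: ", command, call. = FALSE)
  )
  write_run_manifest(out_dir, config, command,
                     seed = if (command == "simulate") paths$seed)
  invisible(result)
}

read_tracks <- function(path) {
  tr <- as.data.frame(data.table::fread(path))
  tr$date <- as.Date(tr$date)
  tr$first_timestamp <- as.POSIXct(tr$first_timestamp, tz = "UTC")
  tr$last_timestamp <- as.POSIXct(tr$last_timestamp, tz = "UTC")
  tr
}

read_summary <- function(path) {
  s <- as.data.frame(data.table::fread(path))
  s$date <- as.Date(s$date)
  s
}

#' Bundled demonstration scene
#'
#' A compact two-site scene used by the `simulate` subcommand and the
#' package examples: one large and one small roost on separate shores,
#' static near-radar clutter, one precipitation day, one radar-failure
#' day, and one roost-free (true-zero) day.
#'
#' @param config A [radar_config()].
#' @param days `Date` vector (default 8 consecutive days).
#' @param seed Integer seed.
#' @param qc A [quant_config()].
#' @return As [simulate_series()].
#' @export
demo_scene <- function(config = radar_config(),
                       days = as.Date("2014-03-01") + 0:7, seed = 1L,
                       qc = quant_config()) {
  profile <- c(0.4, 0.8, 1, 0.7, 0.3)
  site_a <- c(25, 30)
  site_b <- c(-30, -25)
  first_time <- function(d) window_scan_times(d, config)[3]
  mk <- function(center, d, n_birds) {
    roost_spec(center, first_time(d), n_scans = 5, total_birds = n_birds,
               ring_expansion = 1.5, ring_width = 3,
               airborne_fraction = profile)
  }
  pick <- function(ix) days[ix[ix <= length(days)]]
  roosts <- list()
  for (d in as.character(pick(c(1, 2, 4, 6, 7)))) {
    roosts[[length(roosts) + 1L]] <- mk(site_a, as.Date(d), 20000)
  }
  for (d in as.character(pick(c(2, 6, 8)))) {
    roosts[[length(roosts) + 1L]] <- mk(site_b, as.Date(d), 8000)
  }
  simulate_series(
    config, roosts,
    clutter = clutter_spec(eta_level = 300, inner_km = 5, outer_km = 20),
    precip = list(precip_spec(site_a, radius = 10, dbz_level = 45,
                              active_dates = pick(4))),
    days = days, seed = seed, qc = qc,
    failure_dates = pick(5))
}
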