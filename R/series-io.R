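#' @importFrom data.table fread fwrite
NULL

# On-disk container layout
# ------------------------
#   <root>/config.json          radar configuration
#   <root>/day_notes.csv        per-date condition flags
#   <root>/<YYYY-MM-DD>/<HHMMSS>/meta.json       timestamp + elevation list
#   <root>/<YYYY-MM-DD>/<HHMMSS>/sweep_<k>.csv   dBZ grid, azimuth rows,
#                                                NA = no-echo sentinel
# dBZ grids are written with 17 significant digits (%.17g), enough to
# round-trip any double exactly, so write/read is bit-exact.

write_grid <- function(grid, path) {
  txt <- apply(grid, 1, function(row) {
    s <- sprintf("%.17g", row)
    s[is.na(row)] <- "NA"
    paste(s, collapse = ",")
  })
  writeLines(c(paste(sprintf("V%d", seq_len(ncol(grid))), collapse = ","),
               txt), path)
}

read_grid <- function(path) {
  grid <- as.matrix(fread(path, na.strings = "NA"))
  dimnames(grid) <- NULL
  grid
}

config_to_list <- function(config) unclass(config)

config_from_list <- function(x) {
  radar_config(latitude = x$latitude, longitude = x$longitude,
               wavelength = x$wavelength, beamwidth = x$beamwidth,
               range_gate = x$range_gate,
               elevation_angles = as.numeric(x$elevation_angles),
               n_azimuths = x$n_azimuths, n_ranges = x$n_ranges,
               scan_interval = x$scan_interval, utc_offset = x$utc_offset,
               window_start = x$window_start, window_end = x$window_end)
}

#' Write a scan series to a directory
#'
#' Persists the series in the package's plain-text container: one
#' directory per calendar day, one sub-directory per scan volume holding a
#' JSON metadata block plus one CSV reflectivity grid per sweep, with a
#' `config.json` and a `day_notes.csv` manifest at the root. Writing is
#' deterministic: two writes of the same series produce byte-identical
#' payloads.
#'
#' @param series A [scan_series()].
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create ", path, call. = FALSE)
  jsonlite::write_json(config_to_list(series$config),
                       file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  notes <- series$day_notes
  notes$date <- as.character(notes$date)
  fwrite(notes, file.path(path, "day_notes.csv"))
  for (v in series$volumes) {
    day <- format(v$timestamp, "%Y-%m-%d", tz = "UTC")
    hms <- format(v$timestamp, "%H%M%S", tz = "UTC")
    vdir <- file.path(path, day, hms)
    dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(timestamp = format(v$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
           elevations = vapply(v$sweeps, function(s) s$elevation, numeric(1))),
      file.path(vdir, "meta.json"), auto_unbox = TRUE, digits = NA)
    for (k in seq_along(v$sweeps)) {
      write_grid(v$sweeps[[k]]$dbz,
                 file.path(vdir, sprintf("sweep_%02d.csv", k)))
    }
  }
  invisible(path)
}

#' Read a scan series from a directory
#'
#' Inverse of [write_series()]; round-trips dBZ values and metadata
#' bit-exactly. An existing directory with no volume sub-directories yields
#' an empty series.
#'
#' @param path Directory written by [write_series()].
#' @return A [scan_series()].
#' @export
read_series <- function(path) {
  cfg_file <- file.path(path, "config.json")
  if (!file.exists(cfg_file)) {
    stop("series container missing config.json at ", path, call. = FALSE)
  }
  cfg_raw <- jsonlite::read_json(cfg_file, simplifyVector = TRUE)
  for (field in c("wavelength", "beamwidth", "range_gate", "elevation_angles",
                  "n_azimuths", "n_ranges", "scan_interval", "utc_offset")) {
    if (is.null(cfg_raw[[field]])) {
      stop("config.json missing required field: ", field, call. = FALSE)
    }
  }
  config <- config_from_list(cfg_raw)
  notes_file <- file.path(path, "day_notes.csv")
  day_notes <- if (file.exists(notes_file)) {
    n <- as.data.frame(fread(notes_file))
    n$date <- as.Date(n$date)
    n
  } else NULL
  vol_dirs <- sort(list.dirs(path, recursive = TRUE, full.names = TRUE))
  vol_dirs <- vol_dirs[file.exists(file.path(vol_dirs, "meta.json"))]
  volumes <- lapply(vol_dirs, function(vdir) {
    meta <- jsonlite::read_json(file.path(vdir, "meta.json"),
                                simplifyVector = TRUE)
    ts <- as.POSIXct(meta$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                     tz = "UTC")
    sweeps <- lapply(seq_along(meta$elevations), function(k) {
      grid <- read_grid(file.path(vdir, sprintf("sweep_%02d.csv", k)))
      polar_sweep(meta$elevations[k], grid, config)
    })
    scan_volume(ts, sweeps, config)
  })
  if (length(volumes)) {
    ord <- order(vapply(volumes, function(v) as.numeric(v$timestamp),
                        numeric(1)))
    if (is.unsorted(ord)) volumes <- volumes[ord]
    ts <- vapply(volumes, function(v) as.numeric(v$timestamp), numeric(1))
    if (any(diff(ts) <= 0)) {
      stop("volume timestamps are not strictly increasing", call. = FALSE)
    }
  }
  scan_series(volumes, day_notes, config)
}

#' Read/write Label-Studio-style annotation boxes
#'
#' Tabular export with one row per annotated roost box per scan:
#' `scan_id`, `timestamp` (ISO-8601 UTC), `x_min`, `y_min`, `x_max`,
#' `y_max` (km east/north of the radar) and `class` in
#' `{clear, rain, clutter}`. Files in this layout produced by a real
#' annotation session can be substituted for generator output.
#'
#' @param boxes `data.frame` of annotation boxes.
#' @param path CSV file path.
#' @return `read_annotations` returns the boxes `data.frame` with parsed
#'   timestamps; `write_annotations` returns `path` invisibly.
#' @export
write_annotations <- function(boxes, path) {
  out <- boxes
  out$timestamp <- format(as.POSIXct(out$timestamp, tz = "UTC"),
                          "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  fwrite(out, path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- as.data.frame(fread(path))
  needed <- c("scan_id", "timestamp", "x_min", "y_min", "x_max", "y_max",
              "class")
  missing <- setdiff(needed, names(ann))
  if (length(missing)) {
    stop("annotation export missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ann$timestamp <- as.POSIXct(ann$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  ann
}
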