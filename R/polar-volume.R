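#' Radar configuration
#'
#' Describes a fixed-strategy S-band surveillance radar: position, beam
#' geometry, gate spacing, scan schedule, and azimuthal strategy. Defaults
#' follow the Manaus SIPAM radar (S band, 1.8 degree beam, 500 m gates,
#' first sweep at 0.9 degrees, 294- or 360-azimuth sweeps, UTC-4).
#'
#' @param latitude,longitude Radar position in decimal degrees.
#' @param wavelength Radar wavelength in metres.
#' @param beamwidth Half-power beamwidth in degrees (full angle).
#' @param range_gate Radial gate length in metres.
#' @param elevation_angles Sweep elevation angles in degrees, ascending;
#'   the first sweep is the one used for counting.
#' @param n_azimuths Azimuths per sweep, 294 or 360.
#' @param n_ranges Number of range gates per ray.
#' @param scan_interval Minutes between volume scans.
#' @param utc_offset Hours to add to UTC to obtain local clock time.
#' @param window_start,window_end Local-time sampling window in fractional
#'   hours; the window is half-open `[start, end)`.
#'
#' @return An object of class `radar_config`.
#' @export
radar_config <- function(latitude = -3.14889, longitude = -59.99142,
                         wavelength = 0.10, beamwidth = 1.8,
                         range_gate = 500, elevation_angles = 0.9,
                         n_azimuths = 360, n_ranges = 100,
                         scan_interval = 12, utc_offset = -4,
                         window_start = 5, window_end = 8) {
  stopifnot(wavelength > 0, beamwidth > 0, range_gate > 0,
            n_ranges >= 1, scan_interval > 0)
  if (!n_azimuths %in% c(294L, 360L)) {
    stop("n_azimuths must be 294 or 360", call. = FALSE)
  }
  if (is.unsorted(elevation_angles, strictly = TRUE)) {
    stop("elevation_angles must be strictly ascending", call. = FALSE)
  }
  step <- 360 / n_azimuths
  if (abs(n_azimuths * step - 360) > 0.01) {
    stop("azimuth step does not close the circle", call. = FALSE)
  }
  structure(list(
    latitude = latitude, longitude = longitude,
    wavelength = wavelength, beamwidth = beamwidth,
    range_gate = range_gate, elevation_angles = elevation_angles,
    n_azimuths = as.integer(n_azimuths), n_ranges = as.integer(n_ranges),
    scan_interval = scan_interval, utc_offset = utc_offset,
    window_start = window_start, window_end = window_end
  ), class = "radar_config")
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf(
    "<radar_config> %.1f cm / beam %.1f deg / %d az x %d gates of %g m / elevations %s\n",
    x$wavelength * 100, x$beamwidth, x$n_azimuths, x$n_ranges,
    x$range_gate, paste(x$elevation_angles, collapse = ", ")))
  invisible(x)
}

#' Azimuth beam-axis centres for a configuration, degrees clockwise from north.
#' @param config A [radar_config()].
#' @return Numeric vector of length `n_azimuths`.
#' @export
azimuth_centers <- function(config) {
  (seq_len(config$n_azimuths) - 1) * 360 / config$n_azimuths
}

#' Range-gate centres in metres; gate i spans [(i-1) dr, i dr).
#' @param config A [radar_config()].
#' @return Numeric vector of length `n_ranges`.
#' @export
range_centers <- function(config) {
  (seq_len(config$n_ranges) - 0.5) * config$range_gate
}

#' A single polar sweep
#'
#' One full antenna rotation at a fixed elevation. The reflectivity grid is
#' azimuth x range in dBZ; gates with no detectable echo carry `NA` (the
#' no-echo sentinel, deliberately distinct from 0 dBZ, which is a real
#' signal).
#'
#' @param elevation Elevation angle, degrees.
#' @param dbz Matrix `n_azimuths x n_ranges` of reflectivity factor (dBZ),
#'   `NA` meaning no echo.
#' @param config The owning [radar_config()].
#' @return An object of class `polar_sweep`.
#' @export
polar_sweep <- function(elevation, dbz, config) {
  dbz <- as.matrix(dbz)
  if (nrow(dbz) != config$n_azimuths || ncol(dbz) != config$n_ranges) {
    stop(sprintf("dbz grid must be %d x %d, got %d x %d",
                 config$n_azimuths, config$n_ranges, nrow(dbz), ncol(dbz)),
         call. = FALSE)
  }
  structure(list(elevation = elevation, dbz = dbz, config = config),
            class = "polar_sweep")
}

#' A scan volume: one timestamp, one sweep per configured elevation
#'
#' @param timestamp `POSIXct` UTC instant of the volume scan.
#' @param sweeps List of [polar_sweep()]s, elevations matching a prefix of
#'   `config$elevation_angles`.
#' @param config The owning [radar_config()].
#' @return An object of class `scan_volume`.
#' @export
scan_volume <- function(timestamp, sweeps, config) {
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  elevs <- vapply(sweeps, function(s) s$elevation, numeric(1))
  expected <- config$elevation_angles[seq_along(sweeps)]
  if (length(sweeps) == 0 || !isTRUE(all.equal(elevs, expected))) {
    stop("sweep elevations must match a prefix of config$elevation_angles",
         call. = FALSE)
  }
  structure(list(timestamp = timestamp, sweeps = sweeps, config = config),
            class = "scan_volume")
}

#' A time-ordered series of scan volumes with per-day condition notes
#'
#' @param volumes List of [scan_volume()]s, strictly time-ordered.
#' @param day_notes `data.frame` with columns `date` (Date),
#'   `precipitation`, `anomalous_propagation`, `radar_failure` (logical).
#'   Every calendar date appearing in `volumes` must have a row; dates with
#'   no scans (e.g. full radar failure) may also be listed.
#' @param config The shared [radar_config()].
#' @return An object of class `scan_series`.
#' @export
scan_series <- function(volumes, day_notes = NULL, config) {
  if (length(volumes)) {
    ts <- as.POSIXct(vapply(volumes, function(v) as.numeric(v$timestamp),
                            numeric(1)), origin = "1970-01-01", tz = "UTC")
    if (is.unsorted(ts, strictly = TRUE)) {
      stop("volumes must be strictly time-ordered", call. = FALSE)
    }
    dates <- unique(as.Date(ts))
  } else {
    dates <- as.Date(character())
  }
  if (is.null(day_notes)) {
    day_notes <- data.frame(date = dates,
                            precipitation = rep(FALSE, length(dates)),
                            anomalous_propagation = rep(FALSE, length(dates)),
                            radar_failure = rep(FALSE, length(dates)))
  }
  day_notes$date <- as.Date(day_notes$date)
  missing_dates <- setdiff(as.character(dates), as.character(day_notes$date))
  if (length(missing_dates)) {
    stop("day_notes missing entries for: ",
         paste(missing_dates, collapse = ", "), call. = FALSE)
  }
  structure(list(volumes = volumes, day_notes = day_notes, config = config),
            class = "scan_series")
}

#' @export
print.scan_series <- function(x, ...) {
  cat(sprintf("<scan_series> %d volumes over %d day(s)\n",
              length(x$volumes), nrow(x$day_notes)))
  invisible(x)
}

#' Timestamps of the volumes in a series
#' @param series A [scan_series()].
#' @return `POSIXct` vector (UTC).
#' @export
series_timestamps <- function(series) {
  as.POSIXct(vapply(series$volumes, function(v) as.numeric(v$timestamp),
                    numeric(1)), origin = "1970-01-01", tz = "UTC")
}

#' Ground projection of a gate centre
#'
#' Flat-earth projection of a (azimuth, range, elevation) beam position to
#' kilometres east/north of the radar: `x = r sin(az) cos(el)`,
#' `y = r cos(az) cos(el)`. No refraction or earth-curvature model: the
#' projection is intended for close-range roost work only.
#'
#' @param azimuth Degrees clockwise from geographic north (vectorised).
#' @param range Slant range in metres (vectorised).
#' @param elevation Elevation angle in degrees.
#' @return A two-column matrix `cbind(x, y)` in km.
#' @export
gate_center_position <- function(azimuth, range, elevation = 0) {
  if (any(range < 0)) stop("range must be nonnegative", call. = FALSE)
  az <- azimuth * pi / 180
  ce <- cos(elevation * pi / 180)
  r_km <- range / 1000
  cbind(x = r_km * sin(az) * ce, y = r_km * cos(az) * ce)
}

#' Is a UTC instant inside the morning sampling window?
#'
#' The window is a fixed local-clock interval (default 05:00 to 08:00,
#' half-open), the roost-dispersal period of roughly an hour before to two
#' hours after sunrise at near-equatorial latitudes.
#'
#' @param timestamp `POSIXct` UTC instant (vectorised).
#' @param config A [radar_config()] supplying `utc_offset` and the window.
#' @return Logical vector.
#' @export
in_sampling_window <- function(timestamp, config) {
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  local <- timestamp + config$utc_offset * 3600
  hrs <- as.numeric(format(local, "%H", tz = "UTC")) +
    as.numeric(format(local, "%M", tz = "UTC")) / 60 +
    as.numeric(format(local, "%S", tz = "UTC")) / 3600
  hrs >= config$window_start & hrs < config$window_end
}

#' Scheduled in-window scan times for one day
#'
#' @param date A `Date`.
#' @param config A [radar_config()].
#' @return `POSIXct` vector (UTC) of scan start times at `scan_interval`
#'   spacing covering the local sampling window.
#' @export
window_scan_times <- function(date, config) {
  day0 <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC")
  start <- day0 + (config$window_start - config$utc_offset) * 3600
  end <- day0 + (config$window_end - config$utc_offset) * 3600
  out <- seq(from = start, to = end, by = config$scan_interval * 60)
  out[out < end]
}
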