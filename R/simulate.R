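#' Roost dispersal specification
#'
#' A synthetic morning roost dispersal: an expanding ring (doughnut) of
#' reflectivity centred on the roost site, as produced by the synchronized
#' departure of a communal swallow/martin roost. At the k-th scan since
#' `first_scan_time` (k = 0, 1, ...), birds occupy the annulus
#' `[k * ring_expansion, k * ring_expansion + ring_width]` around the
#' centre; the airborne fraction at each scan scales the total.
#'
#' @param center `(x, y)` km east/north of the radar.
#' @param first_scan_time `POSIXct` UTC of the first scan showing the
#'   dispersal.
#' @param n_scans Number of consecutive scans the dispersal spans.
#' @param total_birds True total bird number N_true.
#' @param ring_expansion Ring growth per scan, km.
#' @param ring_width Ring (annulus) width, km.
#' @param airborne_fraction Fraction of N_true aloft at each scan; scalar
#'   or vector of length `n_scans` (default 1).
#' @return An object of class `roost_spec`.
#' @export
roost_spec <- function(center, first_scan_time, n_scans = 5,
                       total_birds = 10000, ring_expansion = 1.5,
                       ring_width = 3, airborne_fraction = 1) {
  stopifnot(length(center) == 2, total_birds > 0, ring_width > 0,
            ring_expansion >= 0, n_scans >= 1)
  max_reach <- sqrt(sum(center^2)) +
    (n_scans - 1) * ring_expansion + ring_width
  if (max_reach > 100) {
    stop("roost ring footprint extends beyond 100 km of the radar",
         call. = FALSE)
  }
  if (sqrt(sum(center^2)) <=
      (n_scans - 1) * ring_expansion + ring_width) {
    stop("roost ring would collide with the radar origin", call. = FALSE)
  }
  airborne_fraction <- rep_len(airborne_fraction, n_scans)
  structure(list(center = as.numeric(center),
                 first_scan_time = as.POSIXct(first_scan_time, tz = "UTC"),
                 n_scans = as.integer(n_scans), total_birds = total_birds,
                 ring_expansion = ring_expansion, ring_width = ring_width,
                 airborne_fraction = airborne_fraction),
            class = "roost_spec")
}

#' Static ground-clutter specification
#'
#' A persistent annulus of near-radar echo (terrain, trees, buildings).
#' The static eta field is drawn once (log-normal texture around
#' `eta_level` between `inner_km` and `outer_km`, zero beyond
#' `max_range`); each scan sees the field times i.i.d. per-gate
#' mean-one log-normal jitter of scale `jitter_sd`.
#'
#' @param eta_level Mean clutter eta, cm2 km-3.
#' @param inner_km,outer_km Annulus bounds, km.
#' @param max_range Hard clutter-region limit, km (default 27.5).
#' @param texture_sd Log-sd of the static per-gate texture.
#' @param jitter_sd Log-sd of the per-scan multiplicative jitter.
#' @return An object of class `clutter_spec`.
#' @export
clutter_spec <- function(eta_level = 300, inner_km = 5, outer_km = 20,
                         max_range = 27.5, texture_sd = 0.3,
                         jitter_sd = 0.2) {
  stopifnot(eta_level >= 0, inner_km >= 0, outer_km > inner_km,
            outer_km <= max_range, jitter_sd >= 0, texture_sd >= 0)
  structure(list(eta_level = eta_level, inner_km = inner_km,
                 outer_km = outer_km, max_range = max_range,
                 texture_sd = texture_sd, jitter_sd = jitter_sd),
            class = "clutter_spec")
}

#' Precipitation blob specification
#'
#' A circular precipitation cell of fixed dBZ overwriting weaker signal on
#' its active dates.
#'
#' @param center `(x, y)` km; the blob is static (one centre) or moving
#'   (`n_scans x 2` matrix of per-scan centres is not needed for the
#'   bundled scenes, so a fixed centre is used).
#' @param radius Blob radius, km.
#' @param dbz_level Blob reflectivity, dBZ (must lie in (-30, 80)).
#' @param active_dates `Date` vector of days the blob is present.
#' @return An object of class `precip_spec`.
#' @export
precip_spec <- function(center, radius = 10, dbz_level = 45,
                        active_dates) {
  stopifnot(length(center) == 2, radius > 0)
  if (dbz_level <= -30 || dbz_level >= 80) {
    stop("dbz_level outside the physical range (-30, 80)", call. = FALSE)
  }
  structure(list(center = as.numeric(center), radius = radius,
                 dbz_level = dbz_level,
                 active_dates = as.Date(active_dates)),
            class = "precip_spec")
}

# gates of a sweep whose centre ground position lies in the annulus
# [r_min, r_max] (km) around center; returns an (az, range) index matrix
gates_in_annulus <- function(config, elevation, center, r_min, r_max) {
  az <- azimuth_centers(config)
  rg <- range_centers(config)
  ce <- cos(elevation * pi / 180)
  x <- outer(sin(az * pi / 180), rg / 1000 * ce)
  y <- outer(cos(az * pi / 180), rg / 1000 * ce)
  d <- sqrt((x - center[1])^2 + (y - center[2])^2)
  which(d >= r_min & d <= r_max, arr.ind = TRUE)
}

roost_annulus <- function(roost, k) {
  inner <- k * roost$ring_expansion
  c(inner = inner, outer = inner + roost$ring_width)
}

roost_box <- function(roost, k, margin = 0.5) {
  reach <- roost_annulus(roost, k)[["outer"]] + margin
  c(x_min = roost$center[1] - reach, y_min = roost$center[2] - reach,
    x_max = roost$center[1] + reach, y_max = roost$center[2] + reach)
}

#' Simulate a scan series with known ground truth
#'
#' Builds a [scan_series()] containing ring-shaped roost dispersals,
#' static ground clutter, and precipitation blobs, together with a
#' ground-truth manifest and matching annotation boxes, so the whole
#' quantification pipeline can be validated against known bird numbers.
#'
#' Roost signal is injected by inverting the quantification forward model:
#' for each roost and scan, the gates of the first sweep whose centres
#' fall in the current annulus receive a uniform density
#' `d = fraction * N_true / sum(V_eff)` where `V_eff = V_full * (1 - f)`
#' is the same overlap-corrected gate volume used by [count_box()] (or the
#' naive `V_full` when `naive_volume = TRUE`, to demonstrate the
#' double-sampling bias the correction removes). Signals are combined
#' additively in linear units; precipitation overwrites weaker signal;
#' gates with no signal carry the no-echo sentinel.
#'
#' @param config A [radar_config()].
#' @param roosts List of [roost_spec()]s.
#' @param clutter A [clutter_spec()] or `NULL`.
#' @param precip List of [precip_spec()]s (possibly empty).
#' @param days `Date` vector of days to simulate.
#' @param seed Integer seed; fixed seed gives a byte-identical series.
#' @param qc The [quant_config()] whose geometry the injection inverts.
#' @param day_notes Optional `data.frame` overriding the generated flags
#'   (columns as in [scan_series()]); by default precipitation days are
#'   flagged from `precip`, and no day is a radar failure.
#' @param failure_dates `Date`s flagged radar failure; their volumes are
#'   omitted from the series.
#' @param naive_volume If `TRUE`, invert with the uncorrected frustum
#'   volume (biases recovered counts low by the overlap fraction).
#' @param box_margin Margin (km) added around the true annulus when
#'   emitting annotation boxes.
#' @return List with elements `series` ([scan_series()]), `manifest`
#'   (ground truth; see below), and `annotations` (boxes as written by
#'   [write_annotations()]).
#'
#' The manifest is a list: `roost_scans` (data.frame: roost id, scan id,
#' timestamp, scan index k, expected airborne birds, true box), `roosts`,
#' `clutter` (including the realized static eta field), `precip`,
#' `day_status` (date, truth status sampled/contaminated/failure/
#' true_zero), and `seed`.
#' @export
simulate_series <- function(config, roosts = list(), clutter = NULL,
                            precip = list(), days, seed = 1L,
                            qc = quant_config(), day_notes = NULL,
                            failure_dates = as.Date(character()),
                            naive_volume = FALSE, box_margin = 0.5) {
  days <- as.Date(days)
  failure_dates <- as.Date(failure_dates)
  geom <- beam_geometry(config, qc)
  v_eff <- if (naive_volume) geom$v_full else geom$v_full * (1 - geom$f)
  elev1 <- config$elevation_angles[1]
  n_az <- config$n_azimuths
  n_rg <- config$n_ranges
  rg_km <- range_centers(config) / 1000

  # static clutter texture, drawn once from the seed
  clutter_field <- NULL
  if (!is.null(clutter)) {
    clutter_field <- local_seed(seed, {
      fld <- matrix(0, n_az, n_rg)
      idx <- gates_in_annulus(config, elev1, c(0, 0),
                              clutter$inner_km,
                              min(clutter$outer_km, clutter$max_range))
      raw <- stats::rlnorm(nrow(idx), meanlog = -clutter$texture_sd^2 / 2,
                           sdlog = clutter$texture_sd)
      fld[idx] <- clutter$eta_level * raw
      fld
    })
  }

  precip_active <- function(p, date) as.Date(date) %in% p$active_dates

  roost_rows <- list()
  volumes <- list()
  scan_counter <- 0L
  for (di in seq_along(days)) {
    date <- days[di]
    if (date %in% failure_dates) next
    times <- window_scan_times(date, config)
    for (ti in seq_along(times)) {
      ts <- times[ti]
      scan_counter <- scan_counter + 1L
      eta_grid <- matrix(0, n_az, n_rg)
      if (!is.null(clutter_field)) {
        jit <- local_seed(seed + 7919L * scan_counter, {
          matrix(stats::rlnorm(n_az * n_rg,
                               meanlog = -clutter$jitter_sd^2 / 2,
                               sdlog = clutter$jitter_sd), n_az, n_rg)
        })
        eta_grid <- eta_grid + clutter_field * jit
      }
      for (ri in seq_along(roosts)) {
        roost <- roosts[[ri]]
        if (ts < roost$first_scan_time) next
        # scan index within the dispersal, by scheduled cadence
        k <- as.integer(round(as.numeric(difftime(ts, roost$first_scan_time,
                                                  units = "mins")) /
                              config$scan_interval))
        if (k < 0 || k >= roost$n_scans) next
        ann <- roost_annulus(roost, k)
        idx <- gates_in_annulus(config, elev1, roost$center,
                                ann[["inner"]], ann[["outer"]])
        if (nrow(idx) == 0) {
          warning(sprintf("roost %d scan k=%d: annulus captures no gates",
                          ri, k))
          next
        }
        target <- roost$airborne_fraction[k + 1] * roost$total_birds
        d <- target / sum(v_eff[idx[, 2]])
        eta_grid[idx] <- eta_grid[idx] + d * qc$sigma
        roost_rows[[length(roost_rows) + 1L]] <- data.frame(
          roost_id = ri,
          scan_id = format(ts, "%Y%m%d_%H%M%S", tz = "UTC"),
          timestamp = ts, k = k, expected_birds = target,
          as.list(roost_box(roost, k, box_margin)))
      }
      z_grid <- eta_to_z(eta_grid, config$wavelength)
      for (p in precip) {
        if (!precip_active(p, date)) next
        idx <- gates_in_annulus(config, elev1, p$center, 0, p$radius)
        zp <- dbz_to_z(p$dbz_level)
        z_grid[idx] <- pmax(z_grid[idx], zp)
      }
      dbz <- ifelse(z_grid > 0, 10 * log10(z_grid), NA_real_)
      sweeps <- list(polar_sweep(elev1, dbz, config))
      volumes[[length(volumes) + 1L]] <- scan_volume(ts, sweeps, config)
    }
  }

  notes <- data.frame(
    date = days,
    precipitation = vapply(days, function(d) {
      any(vapply(precip, precip_active, logical(1), date = d))
    }, logical(1)),
    anomalous_propagation = FALSE,
    radar_failure = days %in% failure_dates)
  if (!is.null(day_notes)) notes <- day_notes

  series <- scan_series(volumes, notes, config)
  roost_scans <- if (length(roost_rows)) {
    do.call(rbind, roost_rows)
  } else {
    data.frame(roost_id = integer(), scan_id = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"),
               k = integer(), expected_birds = numeric(),
               x_min = numeric(), y_min = numeric(),
               x_max = numeric(), y_max = numeric())
  }

  roost_dates <- as.Date(unique(roost_scans$timestamp))
  day_status <- data.frame(date = days, status = vapply(days, function(d) {
    if (d %in% failure_dates) return("failure")
    if (notes$precipitation[notes$date == d] ||
        notes$anomalous_propagation[notes$date == d]) return("contaminated")
    if (d %in% roost_dates) return("sampled")
    "true_zero"
  }, character(1)))

  manifest <- list(roost_scans = roost_scans, roosts = roosts,
                   clutter = clutter, clutter_field = clutter_field,
                   precip = precip, day_status = day_status, seed = seed,
                   naive_volume = naive_volume, box_margin = box_margin)
  list(series = series, manifest = manifest,
       annotations = emit_annotations(manifest))
}

#' Annotation boxes from a ground-truth manifest
#'
#' One box per roost per scan, enclosing the true annulus with the
#' generator's margin. Class is `clear` unless the box intersects an
#' active precipitation blob on that scan (`rain`) or reaches inside the
#' clutter region (`clutter`); rain takes precedence when both apply.
#'
#' @param manifest Manifest from [simulate_series()].
#' @param clutter_range Clutter-region radius used for the class test, km.
#' @return `data.frame` of annotation boxes (see [write_annotations()]).
#' @export
emit_annotations <- function(manifest, clutter_range = 27.5) {
  rs <- manifest$roost_scans
  if (nrow(rs) == 0) {
    return(data.frame(scan_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric(),
                      class = character()))
  }
  cls <- vapply(seq_len(nrow(rs)), function(i) {
    box <- rs[i, c("x_min", "y_min", "x_max", "y_max")]
    date <- as.Date(rs$timestamp[i])
    for (p in manifest$precip) {
      if (!date %in% p$active_dates) next
      if (box_circle_intersects(box, p$center, p$radius)) return("rain")
    }
    if (box_min_range_km(box) < clutter_range) return("clutter")
    "clear"
  }, character(1))
  out <- data.frame(scan_id = rs$scan_id, timestamp = rs$timestamp,
                    x_min = rs$x_min, y_min = rs$y_min,
                    x_max = rs$x_max, y_max = rs$y_max, class = cls)
  out[order(out$timestamp, out$x_min), , drop = FALSE]
}

box_circle_intersects <- function(box, center, radius) {
  cx <- min(max(center[1], box$x_min), box$x_max)
  cy <- min(max(center[2], box$y_min), box$y_max)
  (cx - center[1])^2 + (cy - center[2])^2 <= radius^2
}
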