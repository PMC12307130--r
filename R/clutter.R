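#' Ground-clutter mask
#'
#' Per-(elevation, azimuth-strategy) grid of mean background reflectivity
#' eta (cm2 km-3) within `max_range` of the radar, estimated from the
#' quietest scans of a series and subtracted before counting. Low beams
#' near the radar persistently intercept trees and buildings, producing a
#' ring of mid-level reflectivity that would otherwise inflate counts for
#' roosts caught inside it.
#'
#' @name clutter_mask
NULL

new_clutter_mask <- function(eta, elevation, n_azimuths, max_range,
                             n_scans_used, quantile, source_scans) {
  structure(list(eta = eta, elevation = elevation,
                 n_azimuths = as.integer(n_azimuths), max_range = max_range,
                 n_scans_used = as.integer(n_scans_used),
                 quantile = quantile, source_scans = source_scans),
            class = "clutter_mask")
}

#' @export
print.clutter_mask <- function(x, ...) {
  cat(sprintf(
    "<clutter_mask> elev %.1f deg / %d az, mean of %d scan(s) (q = %g) within %.1f km\n",
    x$elevation, x$n_azimuths, x$n_scans_used, x$quantile, x$max_range))
  invisible(x)
}

check_mask_match <- function(mask, sweep) {
  if (!isTRUE(all.equal(mask$elevation, sweep$elevation)) ||
      mask$n_azimuths != sweep$config$n_azimuths ||
      !identical(dim(mask$eta), dim(sweep$dbz))) {
    stop("clutter mask does not match sweep geometry", call. = FALSE)
  }
  invisible(TRUE)
}

# summed linear reflectivity of the first sweep within max_range; the
# ranking statistic for quiet-scan selection. Summation is done in linear
# units: dBZ sums are dominated by gate count, not signal.
scan_clutter_sum <- function(volume, max_range, statistic = c("eta", "z")) {
  statistic <- match.arg(statistic)
  sweep <- volume$sweeps[[1]]
  rg <- range_centers(volume$config)
  near <- rg / 1000 <= max_range
  z <- dbz_to_z(sweep$dbz[, near, drop = FALSE])
  if (statistic == "eta") {
    sum(z_to_eta(z, volume$config$wavelength))
  } else {
    sum(z)
  }
}

#' Build average ground-clutter masks from the quietest scans
#'
#' Scans are ranked by total summed linear reflectivity within
#' `max_range`; the scans at or below the `quantile` cutoff (the lower 2%
#' by default, ties broken by timestamp) are taken as clutter-only, and
#' their per-gate eta fields are averaged into one mask per elevation for
#' each azimuthal strategy present in the series. No-echo gates enter the
#' average as 0; the mask is zero beyond `max_range`.
#'
#' @param series A [scan_series()].
#' @param quantile Fraction of quietest scans to average (default 0.02).
#'   The number selected is `max(1, floor(quantile * n_scans))`; series
#'   with fewer than `1/quantile` scans trigger a warning because the
#'   cutoff then degenerates to the single quietest scan.
#' @param max_range Clutter-region radius in km (default 27.5).
#' @param statistic Ranking statistic: summed `"eta"` (default) or summed
#'   linear `"z"` (proportional; identical ranking at fixed wavelength).
#' @return Named list of [clutter_mask] objects, one per
#'   `(elevation, n_azimuths)` pair present, named `"<elev>/<n_az>"`.
#' @export
build_masks <- function(series, quantile = 0.02, max_range = 27.5,
                        statistic = c("eta", "z")) {
  statistic <- match.arg(statistic)
  if (quantile <= 0 || quantile >= 1) {
    stop("quantile must be in (0, 1)", call. = FALSE)
  }
  if (length(series$volumes) == 0) {
    warning("no scans in series; no masks built")
    return(structure(list(), class = "clutter_mask_set"))
  }
  strategies <- vapply(series$volumes, function(v) v$config$n_azimuths,
                       integer(1))
  ts <- series_timestamps(series)
  masks <- list()
  for (n_az in sort(unique(strategies))) {
    sel <- which(strategies == n_az)
    n <- length(sel)
    if (n < ceiling(1 / quantile)) {
      warning(sprintf(
        "only %d scan(s) with %d azimuths; quantile cutoff degenerates to %d scan(s)",
        n, n_az, max(1L, floor(quantile * n))))
    }
    sums <- vapply(series$volumes[sel],
                   scan_clutter_sum, numeric(1),
                   max_range = max_range, statistic = statistic)
    k <- max(1L, as.integer(floor(quantile * n + 1e-9)))
    ord <- order(sums, ts[sel])
    chosen <- sel[ord[seq_len(k)]]
    n_elev <- length(series$volumes[[chosen[1]]]$sweeps)
    for (e in seq_len(n_elev)) {
      elev <- series$volumes[[chosen[1]]]$sweeps[[e]]$elevation
      cfg <- series$volumes[[chosen[1]]]$config
      acc <- 0
      for (j in chosen) {
        z <- dbz_to_z(series$volumes[[j]]$sweeps[[e]]$dbz)
        acc <- acc + z_to_eta(z, cfg$wavelength)
      }
      eta_bar <- acc / k
      rg <- range_centers(cfg)
      eta_bar[, rg / 1000 > max_range] <- 0
      key <- paste0(format(elev), "/", n_az)
      masks[[key]] <- new_clutter_mask(
        eta_bar, elev, n_az, max_range, k, quantile,
        format(ts[chosen], "%Y%m%d_%H%M%S", tz = "UTC"))
    }
  }
  structure(masks, class = "clutter_mask_set")
}

#' Look up the mask for a sweep geometry
#' @param masks A mask set from [build_masks()].
#' @param elevation Sweep elevation, degrees.
#' @param n_azimuths Azimuth strategy.
#' @return A [clutter_mask] or `NULL`.
#' @export
find_mask <- function(masks, elevation, n_azimuths) {
  masks[[paste0(format(elevation), "/", n_azimuths)]]
}

#' Subtract a clutter mask from a sweep
#'
#' Gate-wise `eta' = max(eta - eta_bar, 0)` in linear units; negative
#' scatterer densities are meaningless, hence the floor. Gates beyond the
#' mask's `max_range` are unchanged (the mask is zero there).
#'
#' @param sweep A [polar_sweep()].
#' @param mask A matching [clutter_mask].
#' @return Matrix of corrected eta (cm2 km-3), same shape as the sweep
#'   grid; no-echo gates yield 0.
#' @export
apply_mask <- function(sweep, mask) {
  check_mask_match(mask, sweep)
  eta <- z_to_eta(dbz_to_z(sweep$dbz), sweep$config$wavelength)
  pmax(eta - mask$eta, 0)
}

#' Birds attributed to clutter within a box
#'
#' The complement of the masked count: `min(eta, eta_bar)/sigma` integrated
#' over the overlap-corrected gate volumes in the box, i.e. the amount the
#' mask removed, expressed as birds. Satisfies exactly
#' `uncorrected count = corrected count + clutter_birds` on every box.
#'
#' @inheritParams count_box
#' @param mask A matching [clutter_mask].
#' @return Birds removed by the mask within the box.
#' @export
clutter_birds <- function(sweep, mask, box, qc = quant_config(),
                          geom = NULL) {
  count_box(sweep, box, qc, mask = mask, geom = geom)$clutter_birds
}

#' Serialize clutter masks
#'
#' Masks are stored in the same plain-text container style as scan
#' volumes: a JSON provenance block (elevation, strategy, quantile,
#' max_range, source scans) plus a CSV eta grid per mask.
#'
#' @param masks Mask set from [build_masks()].
#' @param path Directory.
#' @return `path` (write) or the mask set (read).
#' @export
write_masks <- function(masks, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  keys <- names(masks)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    stub <- sprintf("mask_%02d", i)
    jsonlite::write_json(
      list(key = keys[i], elevation = m$elevation,
           n_azimuths = m$n_azimuths, max_range = m$max_range,
           n_scans_used = m$n_scans_used, quantile = m$quantile,
           source_scans = m$source_scans),
      file.path(path, paste0(stub, ".json")), auto_unbox = TRUE,
      digits = NA)
    write_grid(m$eta, file.path(path, paste0(stub, ".csv")))
  }
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  metas <- sort(list.files(path, pattern = "^mask_\\d+\\.json$",
                           full.names = TRUE))
  masks <- list()
  for (mf in metas) {
    meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    eta <- read_grid(sub("\\.json$", ".csv", mf))
    masks[[meta$key]] <- new_clutter_mask(
      eta, meta$elevation, meta$n_azimuths, meta$max_range,
      meta$n_scans_used, meta$quantile, meta$source_scans)
  }
  structure(masks, class = "clutter_mask_set")
}
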