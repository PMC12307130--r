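#' Quantification parameters
#'
#' Parameters of the reflectivity-to-bird-count conversion. The default
#' radar cross section of 15.2 cm2 is the published value for a 51 g
#' Purple Martin, the largest Hirundinidae in the Americas, giving
#' conservative counts; [rcs_from_mass()] exposes the mass-RCS power law
#' itself (which yields 15.6 cm2 at 51 g) for users who prefer internal
#' consistency over the published constant. Pixels outside the 5-30 dBZ
#' band are unlikely to be swallows or martins and are discarded; the
#' filter is applied to the raw measured dBZ, before clutter subtraction,
#' so subtraction can never rescue an over-threshold gate.
#'
#' @param sigma Radar cross section per bird, cm2.
#' @param bird_mass Reference bird mass, g (informational; `sigma` rules).
#' @param km2 Dielectric factor |Km|^2 for water at S band.
#' @param dbz_min,dbz_max Raw-dBZ acceptance band, inclusive; use
#'   `-Inf`/`Inf` to disable filtering.
#' @param mc_samples Monte Carlo sample count for the beam-overlap volume.
#' @param mc_seed Seed for the Monte Carlo draw.
#' @param use_first_sweep_only If `TRUE` (default), counts use only the
#'   lowest sweep; higher sweeps either overlap it or overshoot roosts.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(sigma = 15.2, bird_mass = 51, km2 = 0.93,
                         dbz_min = 5, dbz_max = 30,
                         mc_samples = 1e5, mc_seed = 20140101,
                         use_first_sweep_only = TRUE) {
  stopifnot(sigma > 0, km2 > 0, dbz_min < dbz_max, mc_samples >= 1)
  structure(list(sigma = sigma, bird_mass = bird_mass, km2 = km2,
                 dbz_min = dbz_min, dbz_max = dbz_max,
                 mc_samples = as.integer(mc_samples), mc_seed = mc_seed,
                 use_first_sweep_only = use_first_sweep_only),
            class = "quant_config")
}

#' Reflectivity factor (dBZ) to linear Z (mm6 m-3)
#'
#' `Z = 10^(dBZ/10)`; the `NA` no-echo sentinel maps to `Z = 0`.
#'
#' @param dbz Reflectivity factor in dBZ (vectorised; `NA` = no echo).
#' @return Linear reflectivity factor, mm6 m-3.
#' @export
dbz_to_z <- function(dbz) {
  z <- 10^(dbz / 10)
  z[is.na(dbz)] <- 0
  z
}

#' Linear Z to reflectivity eta (cm2 km-3)
#'
#' `eta = 1e3 * pi^5 / lambda_cm^4 * |Km|^2 * Z`, the density of scattering
#' cross section per unit air volume.
#'
#' @param z Linear reflectivity factor, mm6 m-3.
#' @param wavelength Radar wavelength in metres.
#' @param km2 Dielectric factor |Km|^2.
#' @return eta in cm2 km-3.
#' @export
z_to_eta <- function(z, wavelength = 0.10, km2 = 0.93) {
  stopifnot(wavelength > 0)
  lambda_cm <- wavelength * 100
  1e3 * pi^5 / lambda_cm^4 * km2 * z
}

#' Inverse of [z_to_eta()].
#' @param eta eta in cm2 km-3.
#' @inheritParams z_to_eta
#' @return Linear Z, mm6 m-3.
#' @export
eta_to_z <- function(eta, wavelength = 0.10, km2 = 0.93) {
  lambda_cm <- wavelength * 100
  eta / (1e3 * pi^5 / lambda_cm^4 * km2)
}

#' Radar cross section from body mass
#'
#' Power-law relationship `log10 RCS = 0.699 * log10 mass` (RCS in cm2,
#' mass in g).
#'
#' @param mass Body mass in grams; must be positive.
#' @return RCS in cm2.
#' @export
rcs_from_mass <- function(mass) {
  if (any(mass <= 0)) stop("mass must be positive", call. = FALSE)
  10^(0.699 * log10(mass))
}

#' Scatterer density from eta
#' @param eta eta in cm2 km-3.
#' @param sigma Per-bird RCS, cm2.
#' @return Density in birds km-3.
#' @export
eta_to_density <- function(eta, sigma) {
  stopifnot(sigma > 0)
  eta / sigma
}

#' Conical-frustum sampling volume of one range gate
#'
#' The beam between slant ranges `r1` and `r2` is modelled as a conical
#' frustum of full beamwidth `theta`; face radius at range r is
#' `r * tan(theta/2)`. Volume `(pi/3)(r2-r1)(R1^2 + R1 R2 + R2^2)` in km3.
#'
#' @param r1,r2 Gate bounds in metres, `0 <= r1 <= r2`.
#' @param theta Full beamwidth, degrees.
#' @return Volume in km3 (vectorised over `r1`/`r2`).
#' @export
frustum_volume <- function(r1, r2, theta = 1.8) {
  if (any(r1 < 0) || any(r2 < r1)) {
    stop("need 0 <= r1 <= r2", call. = FALSE)
  }
  t <- tan(theta / 2 * pi / 180)
  a <- r1 / 1000
  b <- r2 / 1000
  (pi / 3) * (b - a) * ((a * t)^2 + (a * t) * (b * t) + (b * t)^2)
}

#' Monte Carlo beam-overlap volume
#'
#' Azimuth steps (1 degree for the 360-azimuth strategy, 360/294 for the
#' 294 strategy) are smaller than the 1.8 degree beamwidth, so adjacent
#' beams double-sample a wedge of air. This estimates the intersection
#' volume of two gate frustums whose axes differ by `dphi` in azimuth:
#' points are drawn uniformly in the first frustum (range density
#' proportional to r^2, direction uniform in the cone about the axis) and
#' tested for angular distance at most `theta/2` from the second axis.
#' The fraction is range-independent, so one draw serves every gate.
#'
#' The degenerate cases are analytic: `dphi = 0` gives `f = 1` and
#' `dphi >= theta` gives `f = 0` (tangent or disjoint cones).
#'
#' @param theta Full beamwidth, degrees.
#' @param dphi Azimuthal separation of the two beam axes, degrees.
#' @param r1,r2 Gate bounds, metres.
#' @param n_samples Number of Monte Carlo points.
#' @param seed RNG seed (local to this call).
#' @return List with `v_intersect` (km3), `f` (fraction of the frustum
#'   volume), and `stderr` (binomial standard error of `f`).
#' @export
mc_intersection <- function(theta = 1.8, dphi = 1.0, r1 = 0, r2 = 500,
                            n_samples = 1e5, seed = 1L) {
  stopifnot(n_samples >= 1)
  v_full <- frustum_volume(r1, r2, theta)
  rho <- theta / 2 * pi / 180
  if (dphi == 0) {
    return(list(v_intersect = v_full, f = 1, stderr = 0))
  }
  if (dphi >= theta) {
    return(list(v_intersect = 0, f = 0, stderr = 0))
  }
  f <- local_seed(seed, {
    # directions uniform in the cone about axis a = (0, 1, 0)
    cosa <- stats::runif(n_samples, cos(rho), 1)
    sina <- sqrt(pmax(0, 1 - cosa^2))
    beta <- stats::runif(n_samples, 0, 2 * pi)
    # frame: a = +y; perpendicular plane spanned by x and z
    vx <- sina * cos(beta)
    vy <- cosa
    vz <- sina * sin(beta)
    # second axis at azimuth dphi, same elevation (taken as 0; the test is
    # rotationally symmetric about the radar)
    d <- dphi * pi / 180
    bdotv <- vx * sin(d) + vy * cos(d)
    mean(bdotv >= cos(rho))
  })
  list(v_intersect = v_full * f, f = f,
       stderr = sqrt(f * (1 - f) / n_samples))
}

# run expr under a temporary RNG state
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Monte Carlo union volume of a full ring of beams
#'
#' Estimates the volume of the union of all beams of one sweep over a
#' single range gate: points are drawn uniformly in the spherical shell
#' sector spanning the full azimuth circle, the elevation band
#' `elevation +/- theta/2`, and slant ranges `[r1, r2]`, and tested for
#' angular distance at most `theta/2` from the nearest beam axis. Serves
#' as the independent reference volume in conservation checks of the
#' overlap-halving count: for a uniform density the summed
#' `N_left/2 + N_core + N_right/2` contributions must equal density times
#' this union volume.
#'
#' @param config A [radar_config()].
#' @param r1,r2 Gate bounds, metres.
#' @param n_samples Monte Carlo points.
#' @param seed RNG seed (local to the call).
#' @param elevation Sweep elevation, degrees (default: first configured).
#' @return List with `volume` (km3), `fraction` of the enclosing shell
#'   sector occupied, and `stderr` of the volume.
#' @export
mc_ring_union_volume <- function(config, r1, r2, n_samples = 2e5,
                                 seed = 1L, elevation = NULL) {
  if (is.null(elevation)) elevation <- config$elevation_angles[1]
  rho <- config$beamwidth / 2 * pi / 180
  el <- elevation * pi / 180
  dphi <- 2 * pi / config$n_azimuths
  a_km <- r1 / 1000
  b_km <- r2 / 1000
  omega <- 2 * pi * (sin(el + rho) - sin(el - rho))
  v_enclosing <- omega * (b_km^3 - a_km^3) / 3
  p <- local_seed(seed, {
    lam <- stats::runif(n_samples, 0, 2 * pi)
    sphi <- stats::runif(n_samples, sin(el - rho), sin(el + rho))
    phi <- asin(sphi)
    cphi <- cos(phi)
    # nearest beam axis and its two neighbours
    i0 <- round(lam / dphi)
    hit <- rep(FALSE, n_samples)
    for (off in -1:1) {
      a_i <- (i0 + off) * dphi
      dot <- cphi * cos(el) * cos(lam - a_i) + sphi * sin(el)
      hit <- hit | (dot >= cos(rho))
    }
    mean(hit)
  })
  list(volume = v_enclosing * p, fraction = p,
       stderr = v_enclosing * sqrt(p * (1 - p) / n_samples))
}

#' Cached beam geometry for a configuration
#'
#' Computes, once per (beamwidth, azimuth step, gate size), the per-gate
#' frustum volumes and the Monte Carlo overlap fraction `f` shared by all
#' gates (`f` is range-independent in this regime). The effective volume
#' credited to a beam after splitting each two-beam intersection between
#' its owners is `V_full * (1 - f)`.
#'
#' @param config A [radar_config()].
#' @param qc A [quant_config()] (supplies `mc_samples`, `mc_seed`).
#' @return An object of class `beam_geometry` with elements `v_full`
#'   (vector over range gates, km3), `f`, `f_stderr`, `dphi`, `theta`.
#' @export
beam_geometry <- function(config, qc = quant_config()) {
  dphi <- 360 / config$n_azimuths
  bounds_lo <- (seq_len(config$n_ranges) - 1) * config$range_gate
  bounds_hi <- seq_len(config$n_ranges) * config$range_gate
  v_full <- frustum_volume(bounds_lo, bounds_hi, config$beamwidth)
  mc <- mc_intersection(config$beamwidth, dphi, r1 = 14000, r2 = 14500,
                        n_samples = qc$mc_samples, seed = qc$mc_seed)
  structure(list(v_full = v_full, f = mc$f, f_stderr = mc$stderr,
                 dphi = dphi, theta = config$beamwidth),
            class = "beam_geometry")
}

# gate selection for a box: indices (az, rg) of gates whose centre ground
# position lies in [x_min, x_max] x [y_min, y_max]
gates_in_box <- function(config, elevation, box) {
  az <- azimuth_centers(config)
  rg <- range_centers(config)
  ce <- cos(elevation * pi / 180)
  saz <- sin(az * pi / 180)
  caz <- cos(az * pi / 180)
  r_km <- rg / 1000 * ce
  x <- outer(saz, r_km)
  y <- outer(caz, r_km)
  which(x >= box[["x_min"]] & x <= box[["x_max"]] &
        y >= box[["y_min"]] & y <= box[["y_max"]], arr.ind = TRUE)
}

#' Count birds inside a bounding box on one sweep
#'
#' The pixel-to-bird chain: raw dBZ -> linear Z -> eta -> (optional clutter
#' subtraction in eta) -> density `d = eta/sigma` -> birds. Each gate's
#' density multiplies its overlap-corrected sampling volume: the two-beam
#' intersections on either side are halved between their owners, so a
#' gate contributes `N_left/2 + N_core + N_right/2 = d * V_full * (1 - f)`.
#' Gates are selected by centre-point membership in the box on the ground
#' projection; gates whose raw dBZ falls outside `[dbz_min, dbz_max]` are
#' discarded before any correction. No-echo (`NA`) gates contribute zero.
#'
#' @param sweep A [polar_sweep()]; the first (0.9 degree) sweep when
#'   `qc$use_first_sweep_only`.
#' @param box Named numeric (or one-row data.frame) with `x_min`, `y_min`,
#'   `x_max`, `y_max` in km east/north of the radar.
#' @param qc A [quant_config()].
#' @param mask Optional [clutter_mask()] matching the sweep; `NULL` for no
#'   clutter correction.
#' @param geom Optional precomputed [beam_geometry()]; computed on the fly
#'   if missing.
#' @return List: `birds` (overlap-corrected count), `clutter_birds` (birds
#'   attributed to the subtracted clutter inside the box), `n_gates`
#'   (gates in the box passing the dBZ filter), `n_filtered` (gates
#'   removed by the filter).
#' @export
count_box <- function(sweep, box, qc = quant_config(), mask = NULL,
                      geom = NULL) {
  config <- sweep$config
  if (is.null(geom)) geom <- beam_geometry(config, qc)
  box <- unlist(box[c("x_min", "y_min", "x_max", "y_max")])
  idx <- gates_in_box(config, sweep$elevation, box)
  if (nrow(idx) == 0) {
    warning("box selects no gates inside radar coverage")
    return(list(birds = 0, clutter_birds = 0, n_gates = 0L,
                n_filtered = 0L))
  }
  dbz <- sweep$dbz[idx]
  echo <- !is.na(dbz)
  pass <- !echo | (dbz >= qc$dbz_min & dbz <= qc$dbz_max)
  n_filtered <- sum(!pass)
  idx <- idx[pass, , drop = FALSE]
  dbz <- dbz[pass]
  eta <- z_to_eta(dbz_to_z(dbz), config$wavelength, qc$km2)
  if (!is.null(mask)) {
    check_mask_match(mask, sweep)
    eta_bar <- mask$eta[idx]
    eta_corr <- pmax(eta - eta_bar, 0)
    eta_clut <- pmin(eta, eta_bar)
  } else {
    eta_corr <- eta
    eta_clut <- 0 * eta
  }
  v_eff <- geom$v_full[idx[, 2]] * (1 - geom$f)
  list(birds = sum(eta_corr / qc$sigma * v_eff),
       clutter_birds = sum(eta_clut / qc$sigma * v_eff),
       n_gates = sum(pass), n_filtered = n_filtered)
}

#' Quantify every annotation box in a series
#'
#' Runs [count_box()] for each annotated box against the first sweep of
#' the matching scan volume, producing the per-detection table consumed by
#' the tracking stage.
#'
#' @param series A [scan_series()].
#' @param annotations Annotation boxes as from [emit_annotations()] or
#'   [read_annotations()].
#' @param qc A [quant_config()].
#' @param masks Optional mask set from [build_masks()]; when a box
#'   intersects the clutter region (range below the mask `max_range`) and
#'   no matching mask exists, a warning is emitted (or an error if
#'   `missing_mask = "error"`) and the box is counted uncorrected.
#' @param missing_mask `"warn"` (default) or `"error"`.
#' @return `data.frame` with one row per annotation: scan id, timestamp,
#'   box coordinates, class, `n_gates`, `n_gates_filtered`, `birds`,
#'   `clutter_birds`.
#' @export
quantify_boxes <- function(series, annotations, qc = quant_config(),
                           masks = NULL, missing_mask = c("warn", "error")) {
  missing_mask <- match.arg(missing_mask)
  geom <- beam_geometry(series$config, qc)
  ts <- series_timestamps(series)
  key <- format(ts, "%Y%m%d_%H%M%S", tz = "UTC")
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    ann <- annotations[i, ]
    j <- match(ann$scan_id, key)
    if (is.na(j)) stop("annotation references unknown scan ", ann$scan_id,
                       call. = FALSE)
    sweep <- series$volumes[[j]]$sweeps[[1]]
    mask <- NULL
    if (!is.null(masks)) {
      mask <- find_mask(masks, sweep$elevation, series$config$n_azimuths)
      if (is.null(mask)) {
        box_min_range <- box_min_range_km(ann)
        if (box_min_range < default_clutter_range_km) {
          msg <- paste0("no clutter mask for elevation ", sweep$elevation,
                        " / ", series$config$n_azimuths,
                        " azimuths; box at ", round(box_min_range, 1),
                        " km counted uncorrected")
          if (missing_mask == "error") stop(msg, call. = FALSE)
          warning(msg, call. = FALSE)
        }
      }
    }
    cb <- count_box(sweep, ann, qc, mask = mask, geom = geom)
    data.frame(scan_id = ann$scan_id, timestamp = ann$timestamp,
               x_min = ann$x_min, y_min = ann$y_min,
               x_max = ann$x_max, y_max = ann$y_max,
               class = ann$class, n_gates = cb$n_gates,
               n_gates_filtered = cb$n_filtered, birds = cb$birds,
               clutter_birds = cb$clutter_birds)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

default_clutter_range_km <- 27.5

box_min_range_km <- function(box) {
  dx <- if (box$x_min > 0) box$x_min else if (box$x_max < 0) -box$x_max else 0
  dy <- if (box$y_min > 0) box$y_min else if (box$y_max < 0) -box$y_max else 0
  sqrt(dx^2 + dy^2)
}
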