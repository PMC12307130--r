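# shared fixtures and independent oracles

# independent closed-form oracle for the beam-overlap fraction: in the
# small-angle regime the frustum cross-sections are circles of radius
# rho = theta/2 whose centres sit dphi apart, so the overlap fraction is
# the circle-lens area over the circle area (angles in degrees).
lens_fraction <- function(theta, dphi) {
  rho <- theta / 2
  if (dphi >= 2 * rho) return(0)
  (2 * rho^2 * acos(dphi / (2 * rho)) -
     (dphi / 2) * sqrt(4 * rho^2 - dphi^2)) / (pi * rho^2)
}

# independent frustum-volume oracle: numerically integrate the circular
# cross-section area pi (r tan(theta/2))^2 along the beam
frustum_volume_numint <- function(r1, r2, theta = 1.8) {
  t2 <- tan(theta / 2 * pi / 180)
  stats::integrate(function(r) pi * (r * t2)^2, r1 / 1000, r2 / 1000,
                   rel.tol = 1e-10)$value
}

test_config <- function(n_azimuths = 360, n_ranges = 100, ...) {
  radar_config(n_azimuths = n_azimuths, n_ranges = n_ranges, ...)
}

# a sweep with a constant dBZ value everywhere
uniform_sweep <- function(config, dbz_value) {
  polar_sweep(config$elevation_angles[1],
              matrix(dbz_value, config$n_azimuths, config$n_ranges),
              config)
}

# series of n clutter-free constant-dBZ scans on one day
constant_series <- function(config, dbz_value, n_scans = 3,
                            date = as.Date("2014-01-05")) {
  times <- window_scan_times(date, config)[seq_len(n_scans)]
  vols <- lapply(times, function(ts) {
    scan_volume(ts, list(uniform_sweep(config, dbz_value)), config)
  })
  scan_series(vols, config = config)
}

# one-scan roost scene at a given site/size; returns scene list
single_roost_scene <- function(n_birds, ring_width, center = c(25, 30),
                               config = test_config(), qc = quant_config(),
                               seed = 11L, clutter = NULL, ...) {
  day <- as.Date("2014-03-01")
  t0 <- window_scan_times(day, config)[1]
  roost <- roost_spec(center, t0, n_scans = 1, total_birds = n_birds,
                      ring_expansion = 1.5, ring_width = ring_width)
  simulate_series(config, list(roost), clutter = clutter, precip = list(),
                  days = day, seed = seed, qc = qc, ...)
}

# brute-force linking oracle for one scan transition: enumerates every
# one-to-one matching between previous and current boxes and applies the
# linking rule definitionally -- each current box must be matched to its
# maximal-overlap (then nearest-centroid) available candidate, processed
# in descending overlap order.
oracle_link_step <- function(prev, cur, metric = "area") {
  overlap <- function(a, b) {
    w <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
    h <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
    max(0, w) * max(0, h)
  }
  cdist <- function(a, b) {
    sqrt(((a$x_min + a$x_max) / 2 - (b$x_min + b$x_max) / 2)^2 +
         ((a$y_min + a$y_max) / 2 - (b$y_min + b$y_max) / 2)^2)
  }
  pairs <- expand.grid(ci = seq_len(nrow(cur)), pi = seq_len(nrow(prev)))
  pairs$ov <- mapply(function(ci, pi) overlap(cur[ci, ], prev[pi, ]),
                     pairs$ci, pairs$pi)
  pairs$d <- mapply(function(ci, pi) cdist(cur[ci, ], prev[pi, ]),
                    pairs$ci, pairs$pi)
  pairs <- pairs[pairs$ov > 0, , drop = FALSE]
  pairs <- pairs[order(-pairs$ov, pairs$d), , drop = FALSE]
  match_of <- rep(NA_integer_, nrow(cur))
  used <- logical(nrow(prev))
  for (r in seq_len(nrow(pairs))) {
    ci <- pairs$ci[r]
    pi <- pairs$pi[r]
    if (!is.na(match_of[ci]) || used[pi]) next
    match_of[ci] <- pi
    used[pi] <- TRUE
  }
  match_of
}

# minimal detection table builder
det_row <- function(ts, x_min, y_min, x_max, y_max, birds = 1,
                    class = "clear") {
  data.frame(scan_id = format(ts, "%Y%m%d_%H%M%S", tz = "UTC"),
             timestamp = ts, x_min = x_min, y_min = y_min, x_max = x_max,
             y_max = y_max, class = class, birds = birds)
}

scan_time <- function(i, date = as.Date("2014-03-01"),
                      config = test_config()) {
  window_scan_times(date, config)[i]
}
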