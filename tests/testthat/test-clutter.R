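test_that("mask of a constant clutter field is exact", {
  cfg <- test_config(n_ranges = 60)
  # identical static clutter in every scan, nothing else
  series <- constant_series(cfg, 12, n_scans = 10)
  expect_warning(masks <- build_masks(series), "degenerates")
  m <- find_mask(masks, 0.9, 360)
  expect_s3_class(m, "clutter_mask")
  rg <- range_centers(cfg) / 1000
  inside <- rg <= 27.5
  expect_true(all(abs(m$eta[, inside] - z_to_eta(dbz_to_z(12))) < 1e-9))
  expect_true(all(m$eta[, !inside] == 0))
})

test_that("an all-no-echo series yields an all-zero mask", {
  cfg <- test_config(n_ranges = 30)
  series <- constant_series(cfg, NA_real_, n_scans = 5)
  suppressWarnings(masks <- build_masks(series))
  expect_true(all(find_mask(masks, 0.9, 360)$eta == 0))
})

test_that("the 2% quantile selects exactly the clutter-only scans", {
  # 100 scans: 2 clutter-only, 98 with a roost inside the summation
  # region; rank-by-sum must pick exactly the 2 quiet ones
  cfg <- test_config(n_ranges = 60)
  day <- as.Date("2014-06-01")
  clut <- clutter_spec(eta_level = 300, inner_km = 5, outer_km = 20,
                       jitter_sd = 0.1)
  days <- day + 0:6  # 7 days x 15 scans = 105 scans
  t3 <- window_scan_times(day, cfg)[3]
  roosts <- lapply(as.character(days[-1]), function(d) {
    roost_spec(c(14, 14), window_scan_times(as.Date(d), cfg)[1],
               n_scans = 15, total_birds = 5e4, ring_expansion = 0,
               ring_width = 3)
  })
  scene <- simulate_series(cfg, roosts, clutter = clut, precip = list(),
                           days = days, seed = 21)
  # quiet scans: all 15 of day 1; roosty: the other 90
  masks <- build_masks(scene$series, quantile = 0.02)
  m <- find_mask(masks, 0.9, 360)
  expect_equal(m$n_scans_used, 2L)
  expect_true(all(grepl("^20140601", m$source_scans)))
  # mask approximates the true static field inside the clutter annulus
  rmse <- sqrt(mean((m$eta - scene$manifest$clutter_field)^2))
  expect_lt(rmse, 0.15 * clut$eta_level)
})

test_that("mask error shrinks as more scans are averaged", {
  cfg <- test_config(n_ranges = 56)  # 28 km: clutter region only
  clut <- clutter_spec(eta_level = 300, inner_km = 5, outer_km = 20,
                       jitter_sd = 0.4)
  days <- as.Date("2014-06-01") + 0:6
  scene <- simulate_series(cfg, list(), clutter = clut, precip = list(),
                           days = days, seed = 31)
  truth <- scene$manifest$clutter_field
  rmse_at <- function(q) {
    masks <- build_masks(scene$series, quantile = q)
    m <- find_mask(masks, 0.9, 360)
    sqrt(mean((m$eta - truth)^2))
  }
  r5 <- rmse_at(0.05)   # 5 scans
  r50 <- rmse_at(0.5)   # 52 scans
  expect_lt(r50, r5)
})

test_that("subtraction floors at zero and respects max_range", {
  cfg <- test_config(n_ranges = 60)
  series <- constant_series(cfg, 12, n_scans = 10)
  suppressWarnings(masks <- build_masks(series))
  m <- find_mask(masks, 0.9, 360)
  # eta == mask -> corrected field is identically zero inside max_range
  sweep <- uniform_sweep(cfg, 12)
  corr <- apply_mask(sweep, m)
  rg <- range_centers(cfg) / 1000
  expect_true(all(corr[, rg <= 27.5] == 0))
  expect_true(all(corr[, rg > 27.5] == z_to_eta(dbz_to_z(12))))
  # weaker echo than the mask floors at zero, never negative
  weak <- uniform_sweep(cfg, 5)
  expect_true(all(apply_mask(weak, m)[, rg <= 27.5] == 0))
  # zero mask is the identity
  zero_mask <- m
  zero_mask$eta[] <- 0
  expect_equal(apply_mask(sweep, zero_mask),
               z_to_eta(dbz_to_z(sweep$dbz)))
  # shape mismatch is caught
  small <- test_config(n_ranges = 10)
  expect_error(apply_mask(uniform_sweep(small, 5), m), "match")
})

test_that("counts decompose exactly into corrected + clutter birds", {
  withr::local_seed(77)
  cfg <- test_config(n_ranges = 60)
  series <- constant_series(cfg, 12, n_scans = 10)
  suppressWarnings(masks <- build_masks(series))
  m <- find_mask(masks, 0.9, 360)
  qc <- quant_config(dbz_min = -Inf, dbz_max = Inf)
  geom <- beam_geometry(cfg, qc)
  dbz <- matrix(runif(cfg$n_azimuths * cfg$n_ranges, 0, 25),
                cfg$n_azimuths, cfg$n_ranges)
  dbz[sample(length(dbz), 2000)] <- NA
  sweep <- polar_sweep(0.9, dbz, cfg)
  for (box in list(c(x_min = -30, y_min = -30, x_max = 30, y_max = 30),
                   c(x_min = 5, y_min = -25, x_max = 28, y_max = 3))) {
    plain <- count_box(sweep, box, qc, mask = NULL, geom = geom)
    masked <- count_box(sweep, box, qc, mask = m, geom = geom)
    expect_equal(plain$birds, masked$birds + masked$clutter_birds,
                 tolerance = 1e-12)
  }
  # zero mask removes zero birds
  zero_mask <- m
  zero_mask$eta[] <- 0
  expect_equal(clutter_birds(sweep, zero_mask,
                             c(x_min = -30, y_min = -30, x_max = 30,
                               y_max = 30), qc, geom = geom), 0)
  # echo entirely below the mask: clutter_birds equals the full count
  # (box kept inside the 27.5 km mask region)
  weak <- uniform_sweep(cfg, 5)
  box <- c(x_min = -19, y_min = -19, x_max = 19, y_max = 19)
  full <- count_box(weak, box, qc, geom = geom)$birds
  expect_equal(clutter_birds(weak, m, box, qc, geom = geom), full)
})

test_that("corrected counts are monotone in the mask field", {
  cfg <- test_config(n_ranges = 40)
  qc <- quant_config(dbz_min = -Inf, dbz_max = Inf)
  geom <- beam_geometry(cfg, qc)
  sweep <- uniform_sweep(cfg, 15)
  series <- constant_series(cfg, 10, n_scans = 10)
  suppressWarnings(masks <- build_masks(series))
  m_small <- find_mask(masks, 0.9, 360)
  m_big <- m_small
  m_big$eta <- m_small$eta * 2
  box <- c(x_min = -15, y_min = -15, x_max = 15, y_max = 15)
  expect_gte(count_box(sweep, box, qc, mask = m_small, geom = geom)$birds,
             count_box(sweep, box, qc, mask = m_big, geom = geom)$birds)
})

test_that("masking brings a clutter-contaminated roost count closer to truth", {
  cfg <- test_config(n_ranges = 60)
  qc <- quant_config()
  clut <- clutter_spec(eta_level = 300, inner_km = 5, outer_km = 20,
                       jitter_sd = 0.1)
  # clutter-only days to learn the mask from, then a roost inside the
  # clutter annulus
  days <- as.Date("2014-07-01") + 0:3
  roost_day <- days[4]
  roost <- roost_spec(c(12, 12), window_scan_times(roost_day, cfg)[1],
                      n_scans = 1, total_birds = 2e4, ring_expansion = 0,
                      ring_width = 3)
  scene <- simulate_series(cfg, list(roost), clutter = clut,
                           precip = list(), days = days, seed = 41)
  masks <- build_masks(scene$series, quantile = 0.05)
  m <- find_mask(masks, 0.9, 360)
  ann <- scene$annotations[1, ]
  vol_idx <- match(ann$scan_id,
                   format(series_timestamps(scene$series),
                          "%Y%m%d_%H%M%S", tz = "UTC"))
  sweep <- scene$series$volumes[[vol_idx]]$sweeps[[1]]
  geom <- beam_geometry(cfg, qc)
  unmasked <- count_box(sweep, ann, qc, geom = geom)$birds
  masked <- count_box(sweep, ann, qc, mask = m, geom = geom)$birds
  n_true <- 2e4
  expect_lt(abs(masked - n_true), abs(unmasked - n_true))
  expect_gt(unmasked, n_true)  # clutter inflates the raw count
})

test_that("masks round-trip through their serialized form", {
  cfg <- test_config(n_ranges = 60)
  series <- constant_series(cfg, 12, n_scans = 10)
  suppressWarnings(masks <- build_masks(series))
  path <- withr::local_tempdir()
  write_masks(masks, path)
  back <- read_masks(path)
  expect_equal(names(back), names(masks))
  expect_identical(back[[1]]$eta, masks[[1]]$eta)
  expect_equal(back[[1]]$quantile, masks[[1]]$quantile)
  expect_equal(back[[1]]$source_scans, masks[[1]]$source_scans)
})

test_that("build_masks rejects a bad quantile and empty series warn", {
  cfg <- test_config(n_ranges = 10)
  series <- constant_series(cfg, 5, n_scans = 2)
  expect_error(build_masks(series, quantile = 0), "quantile")
  expect_error(build_masks(series, quantile = 1.2), "quantile")
  empty <- scan_series(list(), config = cfg)
  expect_warning(m <- build_masks(empty), "no scans")
  expect_length(m, 0)
})
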