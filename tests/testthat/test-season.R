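make_summary <- function(dates, status, presence = NULL, totals = NULL) {
  n <- length(dates)
  if (is.null(presence)) presence <- status == "contaminated"
  if (is.null(totals)) {
    totals <- ifelse(status == "sampled", 0, NA_real_)
  }
  data.frame(date = as.Date(dates), status = status,
             n_window_scans = 15L, presence = presence,
             true_zero = status == "sampled" & !presence,
             total_birds = totals)
}

test_that("day classification follows the 6-scan and flag rules", {
  cfg <- test_config(n_ranges = 20)
  day <- as.Date("2014-05-01")
  full <- constant_series(cfg, 10, n_scans = 15, date = day)
  expect_equal(classify_day(full, day), "sampled")
  five <- constant_series(cfg, 10, n_scans = 5, date = day)
  expect_equal(classify_day(five, day), "insufficient")
  six <- constant_series(cfg, 10, n_scans = 6, date = day)
  expect_equal(classify_day(six, day), "sampled")
  rainy <- full
  rainy$day_notes$precipitation <- TRUE
  expect_equal(classify_day(rainy, day), "contaminated")
  dead <- full
  dead$day_notes$radar_failure <- TRUE
  expect_equal(classify_day(dead, day), "radar_failure")
  expect_error(classify_day(full, day + 5), "no day_notes")
})

test_that("daily totals sum peaks and respect contamination", {
  empty <- track_table(link_detections(det_row(scan_time(1), 0, 0, 1, 1)[0, ]))
  expect_equal(daily_total(empty), 0)
  tracks <- data.frame(track_id = 1:3, peak_count = c(31649, 1487, 999),
                       contaminated = c(FALSE, FALSE, TRUE),
                       rain_contaminated = c(FALSE, FALSE, TRUE))
  # the two clean peaks sum; the rain-contaminated one is excluded
  expect_equal(daily_total(tracks), 31649 + 1487)
  # clutter-mixed (rain-free) tracks count by default but can be dropped
  tracks$rain_contaminated[3] <- FALSE
  expect_equal(daily_total(tracks), 31649 + 1487 + 999)
  expect_equal(daily_total(tracks, include_clutter_mixed = FALSE),
               31649 + 1487)
})

test_that("presence bookkeeping reconciles sampled and contaminated days", {
  # category counts as inputs: 178 sampled + 78 contaminated-with-roost
  # days in year one, 145 + 131 in year two
  s2014 <- make_summary(as.Date("2014-01-01") + 0:255,
                        c(rep("sampled", 178), rep("contaminated", 78)))
  s2015 <- make_summary(as.Date("2015-01-01") + 0:275,
                        c(rep("sampled", 145), rep("contaminated", 131)))
  rec <- presence_reconciliation(rbind(s2014, s2015))
  expect_equal(rec$n_presence_absence_days[rec$year == 2014], 256)
  expect_equal(rec$n_presence_absence_days[rec$year == 2015], 276)
  expect_equal(rec$n_sampled + rec$n_contaminated_presence,
               rec$n_presence_absence_days)
})

test_that("true zeros require a sampled day with no detections", {
  s <- make_summary(as.Date("2014-02-01") + 0:2,
                    c("sampled", "contaminated", "sampled"),
                    presence = c(FALSE, TRUE, TRUE))
  cal <- presence_calendar(s)
  expect_true(cal$true_zero[1])
  expect_false(cal$true_zero[2])  # contaminated day with a roost
  expect_false(cal$true_zero[3])  # sampled day with a roost
})

test_that("mean shift recovers designed cluster geometry", {
  # all centroids identical -> one cluster at that point
  tracks1 <- data.frame(track_id = 1:5, date = as.Date("2014-01-01") + 0:4,
                        first_centroid_x = 12, first_centroid_y = -7)
  cl1 <- cluster_roosts(tracks1, bandwidth = 10)
  expect_equal(nrow(cl1$clusters), 1)
  expect_equal(cl1$clusters$centroid_x, 12)
  expect_equal(cl1$clusters$centroid_y, -7)
  expect_equal(cl1$clusters$label, "CL0000")
  # two sites 40 km apart, bandwidth 10 km -> two clusters within 1 km
  withr::local_seed(5)
  n <- 40
  x <- c(rnorm(n, 0, 1), rnorm(n, 40, 1))
  y <- c(rnorm(n, 0, 1), rnorm(n, 0, 1))
  tracks2 <- data.frame(track_id = seq_len(2 * n),
                        date = rep(as.Date("2014-01-01") + 0:19, 4),
                        first_centroid_x = x, first_centroid_y = y)
  cl2 <- cluster_roosts(tracks2, bandwidth = 10)
  expect_equal(nrow(cl2$clusters), 2)
  expect_lt(min(abs(cl2$clusters$centroid_x - 0)), 1)
  expect_lt(min(abs(cl2$clusters$centroid_x - 40)), 1)
  expect_error(cluster_roosts(tracks2, bandwidth = -1), "positive")
})

test_that("cluster labels order by member count and input order is irrelevant", {
  withr::local_seed(6)
  big <- data.frame(track_id = 1:30, date = as.Date("2014-01-01") + 0:29,
                    first_centroid_x = rnorm(30, 0, 0.5),
                    first_centroid_y = rnorm(30, 0, 0.5))
  small <- data.frame(track_id = 31:40, date = as.Date("2014-02-01") + 0:9,
                      first_centroid_x = rnorm(10, 50, 0.5),
                      first_centroid_y = rnorm(10, 0, 0.5))
  ab <- cluster_roosts(rbind(big, small), bandwidth = 10)
  ba <- cluster_roosts(rbind(small, big), bandwidth = 10)
  expect_equal(ab$clusters$label, c("CL0000", "CL0001"))
  expect_equal(ab$clusters$n_tracks, c(30, 10))
  expect_equal(ab$clusters$centroid_x, ba$clusters$centroid_x,
               tolerance = 1e-9)
  expect_lt(abs(ab$clusters$centroid_x[1]), 1)
})

test_that("stability splits clusters by per-year occupancy", {
  # three sites occupied in both years, one in year 1 only
  mk_site <- function(x, dates, id0) {
    data.frame(track_id = id0 + seq_along(dates), date = as.Date(dates),
               first_centroid_x = x, first_centroid_y = 0)
  }
  both_years <- c(as.character(as.Date("2014-01-01") + 0:39),
                  as.character(as.Date("2015-01-01") + 0:39))
  one_year <- as.character(as.Date("2014-06-01") + 0:39)
  tracks <- rbind(mk_site(0, both_years, 0), mk_site(40, both_years, 100),
                  mk_site(80, both_years, 200), mk_site(-40, one_year, 300))
  cl <- cluster_roosts(tracks, bandwidth = 10)
  flags <- stable_vs_satellite(cl, min_days_per_year = 30)
  expect_equal(sum(flags$stable), 3)
  satellite <- flags[!flags$stable, ]
  expect_equal(satellite$centroid_x, -40, tolerance = 1e-6)
  expect_equal(satellite$days_2015, 0)
  # a cluster occupied 200 days each year is stable at any sane threshold
  expect_true(all(flags$stable[flags$days_2014 >= 30 &
                                 flags$days_2015 >= 30]))
})

test_that("sensitivity profiles track the injected floor and ceiling", {
  cfg <- test_config(n_ranges = 30)
  series <- constant_series(cfg, 10, n_scans = 4)
  prof <- sensitivity_profile(series)
  expect_equal(prof$min_dbz, rep(10, 30))
  expect_equal(prof$max_dbz, rep(10, 30))
  # range-dependent floor: min profile recovers it per gate
  withr::local_seed(88)
  floor_dbz <- seq(5, 20, length.out = cfg$n_ranges)
  vols <- lapply(window_scan_times(as.Date("2014-01-05"), cfg)[1:6],
                 function(ts) {
    dbz <- outer(rep(1, cfg$n_azimuths), floor_dbz) +
      matrix(runif(cfg$n_azimuths * cfg$n_ranges, 0, 10),
             cfg$n_azimuths, cfg$n_ranges)
    scan_volume(ts, list(polar_sweep(0.9, dbz, cfg)), cfg)
  })
  series2 <- scan_series(vols, config = cfg)
  prof2 <- sensitivity_profile(series2)
  expect_lt(max(abs(prof2$min_dbz - floor_dbz)), 0.5)
  # a no-echo gate column yields an absent (NaN) profile there
  vols3 <- lapply(series$volumes, function(v) {
    v$sweeps[[1]]$dbz[, 7] <- NA
    v
  })
  prof3 <- sensitivity_profile(scan_series(vols3, config = cfg))
  expect_true(is.nan(prof3$min_dbz[7]))
  expect_equal(prof3$n_scans[7], 0)
})

test_that("region comparison reproduces ratio arithmetic", {
  # identical series give unit ratios
  s <- make_summary(as.Date("2014-01-01") + 0:9, rep("sampled", 10),
                    presence = TRUE, totals = 1000 + 1:10)
  cmp_same <- compare_regions(s, s, 90000, 90000)
  expect_equal(cmp_same$by_year$mean_ratio, 1)
  expect_equal(cmp_same$area_ratio, 1)
  # printed season summaries as inputs: means 71,606 vs 56,956 and areas
  # 90,000 vs 787,229 km2
  a <- make_summary("2014-06-01", "sampled", TRUE, 71606)
  b <- make_summary("2014-06-01", "sampled", TRUE, 56956)
  cmp <- compare_regions(a, b, 90000, 787229)
  expect_equal(round(cmp$by_year$mean_ratio, 2), 1.26)
  expect_equal(round(cmp$area_ratio, 1), 8.7)
  # only sampled days enter the means
  a2 <- rbind(a, make_summary("2014-06-02", "contaminated", TRUE, 1e9))
  expect_equal(compare_regions(a2, b, 1, 1)$by_year$mean_ratio,
               cmp$by_year$mean_ratio)
})
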