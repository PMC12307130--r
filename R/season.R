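#' Classify one day's sampling status
#'
#' A day is `sampled` when it has at least `min_scans` scans inside the
#' morning window and is free of radar failure, precipitation, and
#' anomalous propagation. Days flagged for precipitation or anomalous
#' propagation are `contaminated`: roosts seen on them still count as
#' presences, but their sizes are excluded from quantitative analyses.
#'
#' @param series A [scan_series()].
#' @param date A `Date` with a `day_notes` entry.
#' @param min_scans Minimum in-window scan count (default 6, about a third
#'   of the 15 scheduled scans).
#' @return One of `"sampled"`, `"insufficient"`, `"radar_failure"`,
#'   `"contaminated"`.
#' @export
classify_day <- function(series, date, min_scans = 6) {
  date <- as.Date(date)
  notes <- series$day_notes
  row <- notes[notes$date == date, , drop = FALSE]
  if (nrow(row) == 0) stop("no day_notes entry for ", date, call. = FALSE)
  if (row$radar_failure) return("radar_failure")
  ts <- series_timestamps(series)
  n_window <- sum(as.Date(ts) == date & in_sampling_window(ts, series$config))
  if (n_window < min_scans) return("insufficient")
  if (row$precipitation || row$anomalous_propagation) return("contaminated")
  "sampled"
}

#' Daily total bird count
#'
#' Sum of per-track peak counts for one sampled day. Rain-contaminated
#' tracks are always excluded; clutter-mixed (but rain-free) tracks are
#' included by default since their counts were corrected by the clutter
#' mask.
#'
#' @param tracks Track table (one day) from [track_table()].
#' @param include_clutter_mixed Include clutter-class tracks (default
#'   `TRUE`).
#' @return Summed peak counts; 0 when no eligible tracks.
#' @export
daily_total <- function(tracks, include_clutter_mixed = TRUE) {
  if (nrow(tracks) == 0) return(0)
  keep <- !tracks$rain_contaminated
  if (!include_clutter_mixed) keep <- keep & !tracks$contaminated
  sum(tracks$peak_count[keep])
}

#' Day-level summary of a series
#'
#' Combines [classify_day()], presence, true-zero, and [daily_total()]
#' into the per-day bookkeeping table: `total_birds` is reported only for
#' sampled days; a true zero is a sampled day with full-field visibility
#' (no contamination flag) and no detections anywhere; detections on
#' contaminated days set `presence` but never contribute to totals.
#'
#' @param series A [scan_series()].
#' @param tracks Multi-day track table from [track_table()].
#' @param min_scans Passed to [classify_day()].
#' @param include_clutter_mixed Passed to [daily_total()].
#' @return `data.frame`: `date`, `status`, `n_window_scans`, `presence`,
#'   `true_zero`, `total_birds` (`NA` unless sampled).
#' @export
summarize_days <- function(series, tracks, min_scans = 6,
                           include_clutter_mixed = TRUE) {
  dates <- sort(series$day_notes$date)
  ts <- series_timestamps(series)
  in_win <- in_sampling_window(ts, series$config)
  rows <- lapply(dates, function(d) {
    status <- classify_day(series, d, min_scans)
    day_tracks <- tracks[tracks$date == d, , drop = FALSE]
    presence <- nrow(day_tracks) > 0
    sampled <- status == "sampled"
    data.frame(date = d, status = status,
               n_window_scans = sum(as.Date(ts) == d & in_win),
               presence = presence,
               true_zero = sampled && !presence,
               total_birds = if (sampled) {
                 daily_total(day_tracks, include_clutter_mixed)
               } else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Presence / true-zero calendar
#'
#' @param summaries Daily summary table from [summarize_days()].
#' @return `data.frame`: `date`, `presence`, `true_zero`.
#' @export
presence_calendar <- function(summaries) {
  summaries[, c("date", "presence", "true_zero")]
}

#' Presence/absence bookkeeping reconciliation
#'
#' Per year: days usable for roost-size estimation (`sampled`), days
#' contaminated by weather but with a roost presence, and their sum - the
#' total days entering the presence/absence analysis - plus true-zero
#' counts. Sampled and contaminated-with-presence day counts must
#' reconcile additively into the presence/absence total.
#'
#' @param summaries Daily summary table from [summarize_days()].
#' @return `data.frame` per year: `year`, `n_sampled`,
#'   `n_contaminated_presence`, `n_presence_absence_days`, `n_true_zero`.
#' @export
presence_reconciliation <- function(summaries) {
  yr <- as.integer(format(summaries$date, "%Y"))
  rows <- lapply(sort(unique(yr)), function(y) {
    s <- summaries[yr == y, , drop = FALSE]
    n_sampled <- sum(s$status == "sampled")
    n_cp <- sum(s$status == "contaminated" & s$presence)
    data.frame(year = y, n_sampled = n_sampled,
               n_contaminated_presence = n_cp,
               n_presence_absence_days = n_sampled + n_cp,
               n_true_zero = sum(s$true_zero))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# flat-kernel mean shift over 2-D points; returns integer mode labels and
# the mode coordinates. Fixed-point iteration per point, modes merged at
# bandwidth/2. Deterministic: no RNG, merge order by mode discovery.
mean_shift <- function(pts, bandwidth, tol = 1e-6, max_iter = 500) {
  n <- nrow(pts)
  modes <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    m <- pts[i, ]
    for (it in seq_len(max_iter)) {
      d2 <- (pts[, 1] - m[1])^2 + (pts[, 2] - m[2])^2
      nb <- d2 <= bandwidth^2
      m_new <- c(mean(pts[nb, 1]), mean(pts[nb, 2]))
      if (sum((m_new - m)^2) < tol^2) {
        m <- m_new
        break
      }
      m <- m_new
    }
    modes[i, ] <- m
  }
  centers <- matrix(numeric(0), 0, 2)
  labels <- integer(n)
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (nrow(centers)) {
      d2 <- (centers[, 1] - modes[i, 1])^2 + (centers[, 2] - modes[i, 2])^2
      j <- which(d2 <= (bandwidth / 2)^2)
      if (length(j)) {
        labels[i] <- j[1]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      centers <- rbind(centers, modes[i, ])
      labels[i] <- nrow(centers)
    }
  }
  # recompute centres as member means for stability
  for (j in seq_len(nrow(centers))) {
    centers[j, ] <- c(mean(pts[labels == j, 1]), mean(pts[labels == j, 2]))
  }
  list(labels = labels, centers = centers)
}

#' Cluster roost locations by mean shift
#'
#' Flat-kernel mean-shift clustering of track first-centroids, revealing
#' the roosting regions used repeatedly across a season. Labels are
#' assigned in descending order of member count (ties broken by centroid
#' x, i.e. longitude offset) and formatted `CL0000`, `CL0001`, ...
#'
#' @param tracks Track table from [track_table()] (needs
#'   `first_centroid_x/y` and `date`).
#' @param bandwidth Kernel radius in km (default 10).
#' @return List of class `roost_cluster_set`: `clusters` (`data.frame`:
#'   `label`, `centroid_x`, `centroid_y`, `n_tracks`, per-year occupancy
#'   columns `days_<year>`), `assignments` (per track: `track_id`,
#'   `label`), `bandwidth`.
#' @export
cluster_roosts <- function(tracks, bandwidth = 10) {
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  if (nrow(tracks) == 0) stop("no tracks to cluster", call. = FALSE)
  pts <- cbind(tracks$first_centroid_x, tracks$first_centroid_y)
  ms <- mean_shift(pts, bandwidth)
  years <- sort(unique(format(tracks$date, "%Y")))
  counts <- tabulate(ms$labels, nbins = nrow(ms$centers))
  ord <- order(-counts, ms$centers[, 1])
  relabel <- match(seq_along(counts), ord)
  labels_chr <- sprintf("CL%04d", relabel[ms$labels] - 1)
  clusters <- do.call(rbind, lapply(seq_along(ord), function(r) {
    j <- ord[r]
    members <- ms$labels == j
    row <- data.frame(label = sprintf("CL%04d", r - 1),
                      centroid_x = ms$centers[j, 1],
                      centroid_y = ms$centers[j, 2],
                      n_tracks = sum(members))
    for (y in years) {
      row[[paste0("days_", y)]] <-
        length(unique(tracks$date[members & format(tracks$date, "%Y") == y]))
    }
    row
  }))
  structure(list(clusters = clusters,
                 assignments = data.frame(track_id = tracks$track_id,
                                          label = labels_chr),
                 bandwidth = bandwidth, years = years),
            class = "roost_cluster_set")
}

#' @export
print.roost_cluster_set <- function(x, ...) {
  cat(sprintf("<roost_cluster_set> %d cluster(s), bandwidth %g km\n",
              nrow(x$clusters), x$bandwidth))
  print(x$clusters)
  invisible(x)
}

#' Stable versus satellite roost clusters
#'
#' A cluster is `stable` when it is occupied on at least
#' `min_days_per_year` distinct days in every observed year; otherwise it
#' is a satellite (transiently used) roost. The threshold is an artifact
#' convention (default 30 days) and is recorded in the output.
#'
#' @param clusters A `roost_cluster_set` from [cluster_roosts()].
#' @param min_days_per_year Occupancy threshold per year.
#' @return The cluster `data.frame` with a logical `stable` column and the
#'   threshold in attribute `min_days_per_year`.
#' @export
stable_vs_satellite <- function(clusters, min_days_per_year = 30) {
  cl <- clusters$clusters
  day_cols <- paste0("days_", clusters$years)
  cl$stable <- apply(cl[, day_cols, drop = FALSE] >= min_days_per_year, 1,
                     all)
  attr(cl, "min_days_per_year") <- min_days_per_year
  cl
}

#' Radar sensitivity profile
#'
#' Per range gate: the per-scan minimum and maximum detected (non-sentinel)
#' reflectivity over azimuths, averaged across the sampled scans. Used to
#' compare the detection floors of two radars before comparing their
#' counts. Scan sampling is systematic (every `1/sample_fraction`-th scan)
#' so the profile is deterministic.
#'
#' @param series A [scan_series()].
#' @param sample_fraction Fraction of scans to profile (default 1).
#' @return `data.frame`: `range_km`, `min_dbz`, `max_dbz`, `n_scans`
#'   (scans with any echo at that gate). Gates with no echo in any sampled
#'   scan have `NA` profiles.
#' @export
sensitivity_profile <- function(series, sample_fraction = 1) {
  stopifnot(sample_fraction > 0, sample_fraction <= 1)
  n <- length(series$volumes)
  if (n == 0) stop("empty series", call. = FALSE)
  take <- unique(round(seq(1, n, by = 1 / sample_fraction)))
  rg <- range_centers(series$config) / 1000
  mins <- maxs <- matrix(NA_real_, length(take), length(rg))
  for (i in seq_along(take)) {
    dbz <- series$volumes[[take[i]]]$sweeps[[1]]$dbz
    any_echo <- colSums(!is.na(dbz)) > 0
    mins[i, any_echo] <- apply(dbz[, any_echo, drop = FALSE], 2, min,
                               na.rm = TRUE)
    maxs[i, any_echo] <- apply(dbz[, any_echo, drop = FALSE], 2, max,
                               na.rm = TRUE)
  }
  data.frame(range_km = rg,
             min_dbz = colMeans(mins, na.rm = TRUE),
             max_dbz = colMeans(maxs, na.rm = TRUE),
             n_scans = colSums(!is.na(mins)))
}

#' Compare daily roost abundance between two regions
#'
#' Computes per-year mean and standard deviation of daily totals over
#' sampled days for each region, the ratio of means (region A over region
#' B, per common year), and the sampled-area ratio (B over A).
#'
#' @param summaries_a,summaries_b Daily summary tables (columns `date`,
#'   `status`, `total_birds`) for the two regions.
#' @param area_a,area_b Sampled areas, km2.
#' @return List of class `region_comparison`: `by_year` (`data.frame`:
#'   `year`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `mean_ratio`),
#'   `area_a`, `area_b`, `area_ratio` (= `area_b / area_a`).
#' @export
compare_regions <- function(summaries_a, summaries_b, area_a, area_b) {
  stopifnot(area_a > 0, area_b > 0)
  stats_by_year <- function(s) {
    s <- s[s$status == "sampled" & !is.na(s$total_birds), , drop = FALSE]
    if (nrow(s) == 0) stop("no sampled days", call. = FALSE)
    yr <- as.integer(format(as.Date(s$date), "%Y"))
    do.call(rbind, lapply(sort(unique(yr)), function(y) {
      v <- s$total_birds[yr == y]
      data.frame(year = y, mean = mean(v), sd = stats::sd(v), n_days = length(v))
    }))
  }
  a <- stats_by_year(summaries_a)
  b <- stats_by_year(summaries_b)
  years <- intersect(a$year, b$year)
  by_year <- do.call(rbind, lapply(years, function(y) {
    ra <- a[a$year == y, ]
    rb <- b[b$year == y, ]
    data.frame(year = y, mean_a = ra$mean, sd_a = ra$sd, n_days_a = ra$n_days,
               mean_b = rb$mean, sd_b = rb$sd, n_days_b = rb$n_days,
               mean_ratio = ra$mean / rb$mean)
  }))
  structure(list(by_year = by_year, region_a = a, region_b = b,
                 area_a = area_a, area_b = area_b,
                 area_ratio = area_b / area_a),
            class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("<region_comparison> area ratio B/A = %.2f\n", x$area_ratio))
  print(x$by_year)
  invisible(x)
}
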