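#' Link per-scan detections into dispersal tracks
#'
#' A track is the chain of detections of one roost dispersal across
#' consecutive scans. Each detection in scan t is assigned to the track of
#' the previous-scan detection with which its bounding box overlaps the
#' most (raw intersection area by default); when the best overlap is tied,
#' the candidate with the nearest centroid wins. Matching is greedy and
#' one-to-one in descending overlap order, so a previous-scan detection is
#' claimed by at most one successor; detections with no positive overlap
#' (and greedy losers) start new tracks. Tracks never bridge gaps: only
#' the immediately previous scan is considered.
#'
#' @param detections `data.frame` of per-scan detections (as from
#'   [quantify_boxes()]): `scan_id`, `timestamp`, box coordinates,
#'   `class`, `birds`. All detections must belong to one calendar day's
#'   sampling window; mixing days is an error (use [track_series()] for
#'   multi-day tables).
#' @param metric `"area"` (raw intersection area, default) or `"iou"`
#'   (intersection over union).
#' @return The input with columns `track_id` (integer), `centroid_x`,
#'   `centroid_y` added.
#' @export
link_detections <- function(detections, metric = c("area", "iou")) {
  metric <- match.arg(metric)
  det <- detections
  if (nrow(det) == 0) {
    det$track_id <- integer(0)
    det$centroid_x <- det$centroid_y <- numeric(0)
    return(det)
  }
  if (length(unique(as.Date(as.POSIXct(det$timestamp, tz = "UTC")))) > 1) {
    stop("detections span multiple days; link one day at a time",
         call. = FALSE)
  }
  det$centroid_x <- (det$x_min + det$x_max) / 2
  det$centroid_y <- (det$y_min + det$y_max) / 2
  # deterministic processing order regardless of input row order
  ord <- order(det$timestamp, det$centroid_x, det$centroid_y)
  det <- det[ord, , drop = FALSE]
  det$track_id <- NA_integer_
  scans <- unique(det$timestamp)
  next_track <- 1L
  prev_idx <- integer(0)
  for (s in seq_along(scans)) {
    cur_idx <- which(det$timestamp == scans[s])
    if (length(prev_idx) == 0) {
      det$track_id[cur_idx] <- seq(next_track, length.out = length(cur_idx))
      next_track <- next_track + length(cur_idx)
      prev_idx <- cur_idx
      next
    }
    pairs <- expand.grid(ci = cur_idx, pi = prev_idx)
    pairs$overlap <- mapply(function(ci, pi) {
      box_overlap(det[ci, ], det[pi, ], metric)
    }, pairs$ci, pairs$pi)
    pairs <- pairs[pairs$overlap > 0, , drop = FALSE]
    pairs$dist <- sqrt((det$centroid_x[pairs$ci] - det$centroid_x[pairs$pi])^2 +
                       (det$centroid_y[pairs$ci] - det$centroid_y[pairs$pi])^2)
    pairs <- pairs[order(-pairs$overlap, pairs$dist,
                         det$centroid_x[pairs$ci], det$centroid_y[pairs$ci],
                         det$centroid_x[pairs$pi]), , drop = FALSE]
    claimed_prev <- claimed_cur <- integer(0)
    for (r in seq_len(nrow(pairs))) {
      ci <- pairs$ci[r]; pi <- pairs$pi[r]
      if (ci %in% claimed_cur || pi %in% claimed_prev) next
      det$track_id[ci] <- det$track_id[pi]
      claimed_cur <- c(claimed_cur, ci)
      claimed_prev <- c(claimed_prev, pi)
    }
    losers <- setdiff(cur_idx, claimed_cur)
    if (length(losers)) {
      det$track_id[losers] <- seq(next_track, length.out = length(losers))
      next_track <- next_track + length(losers)
    }
    prev_idx <- cur_idx
  }
  det
}

box_overlap <- function(a, b, metric = "area") {
  w <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  h <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  inter <- max(0, w) * max(0, h)
  if (metric == "iou" && inter > 0) {
    areas <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
      (b$x_max - b$x_min) * (b$y_max - b$y_min)
    return(inter / (areas - inter))
  }
  inter
}

#' Link detections day by day
#'
#' Splits a multi-day detection table by (UTC) calendar date, links each
#' day with [link_detections()], and offsets track ids so they stay unique
#' across the table. Day-to-day site fidelity is deliberately not bridged
#' by tracking; it is handled by spatial clustering.
#'
#' @inheritParams link_detections
#' @return Detection table with globally unique `track_id`.
#' @export
track_series <- function(detections, metric = c("area", "iou")) {
  metric <- match.arg(metric)
  if (nrow(detections) == 0) return(link_detections(detections, metric))
  dates <- as.Date(as.POSIXct(detections$timestamp, tz = "UTC"))
  out <- list()
  offset <- 0L
  for (d in as.character(sort(unique(dates)))) {
    day <- link_detections(detections[as.character(dates) == d, ,
                                      drop = FALSE], metric)
    day$track_id <- day$track_id + offset
    offset <- offset + length(unique(day$track_id))
    out[[length(out) + 1L]] <- day
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Peak count of a track
#' @param birds Numeric vector of member detections' bird counts.
#' @return The maximum count.
#' @export
track_peak <- function(birds) {
  if (length(birds) == 0) stop("empty track", call. = FALSE)
  max(birds)
}

#' Per-track summary table
#'
#' @param detections Linked detections from [link_detections()] or
#'   [track_series()].
#' @return `data.frame` with one row per track: `track_id`, `date`,
#'   `n_detections`, `first_timestamp`, `last_timestamp`,
#'   `first_centroid_x/y` (centroid of the earliest detection),
#'   `peak_count`, `contaminated` (any member class != clear),
#'   `rain_contaminated` (any member class == rain).
#' @export
track_table <- function(detections) {
  if (nrow(detections) == 0) {
    return(data.frame(track_id = integer(), date = as.Date(character()),
                      n_detections = integer(),
                      first_timestamp = as.POSIXct(character(), tz = "UTC"),
                      last_timestamp = as.POSIXct(character(), tz = "UTC"),
                      first_centroid_x = numeric(),
                      first_centroid_y = numeric(),
                      peak_count = numeric(), contaminated = logical(),
                      rain_contaminated = logical()))
  }
  rows <- lapply(split(detections, detections$track_id), function(tr) {
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    data.frame(track_id = tr$track_id[1],
               date = as.Date(tr$timestamp[1]),
               n_detections = nrow(tr),
               first_timestamp = tr$timestamp[1],
               last_timestamp = tr$timestamp[nrow(tr)],
               first_centroid_x = tr$centroid_x[1],
               first_centroid_y = tr$centroid_y[1],
               peak_count = track_peak(tr$birds),
               contaminated = any(tr$class != "clear"),
               rain_contaminated = any(tr$class == "rain"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
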