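#' Detection configuration for feeding-event fusion
#'
#' Constants of the ACC/GPS fusion step, defaulting to the field rules:
#' a 30-min sliding window in which at least a third of bursts must be
#' 'true feeding', a minimum feeding-cluster duration of 30 min, a maximum
#' within-cluster gap of 120 min, a 50-m chaining distance for GPS
#' clusters (minimum duration 30 min), a 50-m centroid-merge distance, GPS
#' fix intervals of 3 or 15 min for boundary correction, and a 60-min
#' pre-event scan for high-ACC-variation (trotting/running) bursts.
#'
#' @param window_min Sliding-window length, minutes.
#' @param feeding_fraction Minimum fraction of true-feeding bursts per
#'   window.
#' @param min_cluster_min Minimum feeding/GPS cluster duration, minutes.
#' @param max_gap_min Maximum gap between feeding candidates merged into
#'   one cluster, minutes.
#' @param gps_dist_m Maximum distance between consecutive fixes of one GPS
#'   cluster, metres.
#' @param centroid_merge_m Centroid distance below which overlapping GPS
#'   clusters are merged, metres.
#' @param pre_event_scan_min Length of the pre-event scan window, minutes.
#' @param walk_run_min Minimum duration of a walking cluster, minutes.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(window_min = 30, feeding_fraction = 1 / 3,
                             min_cluster_min = 30, max_gap_min = 120,
                             gps_dist_m = 50, centroid_merge_m = 50,
                             pre_event_scan_min = 60, walk_run_min = 15) {
  vals <- c(window_min, feeding_fraction, min_cluster_min, max_gap_min,
            gps_dist_m, centroid_merge_m, pre_event_scan_min, walk_run_min)
  stopifnot(all(vals > 0))
  structure(
    list(window_min = window_min, feeding_fraction = feeding_fraction,
         min_cluster_min = min_cluster_min, max_gap_min = max_gap_min,
         gps_dist_m = gps_dist_m, centroid_merge_m = centroid_merge_m,
         pre_event_scan_min = pre_event_scan_min,
         walk_run_min = walk_run_min),
    class = "detection_config"
  )
}

#' Great-circle distance in metres
#'
#' Haversine distance on a sphere of mean Earth radius 6,371,008.8 m.
#' Vectorised; symmetric; zero only for identical points.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in WGS84 decimal degrees.
#' @return Distance(s) in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

#' Identify 'true feeding' bursts
#'
#' A burst counts as true feeding when the SVM, the mean ensemble, or the
#' majority ensemble labels it F — the predictors that carry the feeding
#' signal most reliably.
#'
#' @param preds A prediction set ([predict_bursts()]).
#' @return Logical vector, one element per burst.
#' @export
true_feeding <- function(preds) {
  preds$svm_label == "F" | preds$mean_label == "F" |
    preds$majority_label == "F"
}

# High-ACC-variation bursts (trotting/running), same predictor subset as
# true feeding.
high_acc_burst <- function(preds) {
  preds$svm_label == "T" | preds$mean_label == "T" |
    preds$majority_label == "T"
}

mins <- function(m) as.difftime(m, units = "mins")

#' Find feeding clusters in a chronological prediction stream
#'
#' Slides a time window of `cfg$window_min` minutes burst-by-burst over
#' one animal's predictions. A window anchored at a burst covers all
#' bursts in `[t, t + window)`; it is feeding-dense when its true-feeding
#' count reaches `ceiling(feeding_fraction x bursts in window)`. Bursts
#' covered by any dense window form candidate intervals, each trimmed to
#' its first and last true-feeding burst; candidates separated by at most
#' `max_gap_min` are merged, and merged candidates shorter than
#' `min_cluster_min` are discarded.
#'
#' @param preds Prediction set for a single animal, sorted by time.
#' @param cfg A [detection_config()].
#' @return A tibble: `animal_id`, `start`, `end`, `n_bursts`,
#'   `n_true_feeding`, `member_times` (list of burst times in the cluster).
#' @export
find_feeding_clusters <- function(preds, cfg = detection_config()) {
  stopifnot(length(unique(preds$animal_id)) <= 1)
  n <- nrow(preds)
  empty <- tibble(animal_id = character(), start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  n_bursts = integer(), n_true_feeding = integer(),
                  member_times = list())
  if (n == 0) return(empty)
  if (is.unsorted(preds$start_time)) stop("predictions must be time-sorted")
  t <- preds$start_time
  tf <- true_feeding(preds)

  covered <- logical(n)
  win <- mins(cfg$window_min)
  hi <- 1L
  cum_tf <- cumsum(tf)
  for (i in seq_len(n)) {
    if (hi < i) hi <- i
    while (hi < n && t[hi + 1L] < t[i] + win) hi <- hi + 1L
    n_in <- hi - i + 1L
    n_tf <- cum_tf[hi] - cum_tf[i] + tf[i]
    if (n_tf >= ceiling(cfg$feeding_fraction * n_in)) {
      covered[i:hi] <- TRUE
    }
  }
  if (!any(covered & tf)) return(empty)

  # maximal runs of covered bursts -> candidate intervals trimmed to
  # true-feeding bursts
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- list()
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    tf_idx <- idx[tf[idx]]
    if (length(tf_idx) == 0) next
    cand[[length(cand) + 1L]] <- c(min(tf_idx), max(tf_idx))
  }
  if (length(cand) == 0) return(empty)

  # merge candidates separated by <= max_gap, then apply duration filter
  merged <- list(cand[[1]])
  for (c_ in cand[-1]) {
    last <- merged[[length(merged)]]
    if (difftime(t[c_[1]], t[last[2]], units = "mins") <= cfg$max_gap_min) {
      merged[[length(merged)]] <- c(last[1], c_[2])
    } else {
      merged[[length(merged) + 1L]] <- c_
    }
  }
  rows <- list()
  for (m in merged) {
    dur <- difftime(t[m[2]], t[m[1]], units = "mins")
    if (dur < cfg$min_cluster_min) next
    idx <- m[1]:m[2]
    rows[[length(rows) + 1L]] <- tibble(
      animal_id = preds$animal_id[1],
      start = t[m[1]], end = t[m[2]],
      n_bursts = length(idx), n_true_feeding = sum(tf[idx]),
      member_times = list(t[idx])
    )
  }
  if (length(rows) == 0) empty else dplyr::bind_rows(rows)
}

#' Find GPS clusters by consecutive-fix chaining
#'
#' Greedy chain over one animal's time-ordered fixes: the current cluster
#' is extended while the next fix lies within `gps_dist_m` of the previous
#' fix, and closed otherwise. Chains lasting at least `min_cluster_min`
#' minutes are kept; the centroid is the arithmetic mean of member
#' latitudes and longitudes.
#'
#' @param fixes Tibble of one animal's fixes (`animal_id`, `time`, `lat`,
#'   `lon`), time-sorted.
#' @param cfg A [detection_config()].
#' @return A tibble: `animal_id`, `start`, `end`, `n_fixes`,
#'   `centroid_lat`, `centroid_lon`, `member_idx` (list of row indices
#'   into `fixes`).
#' @export
find_gps_clusters <- function(fixes, cfg = detection_config()) {
  stopifnot(length(unique(fixes$animal_id)) <= 1)
  empty <- tibble(animal_id = character(),
                  start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  n_fixes = integer(), centroid_lat = double(),
                  centroid_lon = double(), member_idx = list())
  n <- nrow(fixes)
  if (n == 0) return(empty)
  if (is.unsorted(fixes$time)) stop("fixes must be time-sorted")

  d <- if (n > 1) {
    haversine_m(fixes$lat[-n], fixes$lon[-n], fixes$lat[-1], fixes$lon[-1])
  } else numeric(0)
  breaks <- c(which(d > cfg$gps_dist_m), n)
  rows <- list()
  lo <- 1L
  for (b in breaks) {
    idx <- lo:b
    lo <- b + 1L
    dur <- difftime(fixes$time[max(idx)], fixes$time[min(idx)],
                    units = "mins")
    if (dur >= cfg$min_cluster_min) {
      rows[[length(rows) + 1L]] <- tibble(
        animal_id = fixes$animal_id[1],
        start = fixes$time[min(idx)], end = fixes$time[max(idx)],
        n_fixes = length(idx),
        centroid_lat = mean(fixes$lat[idx]),
        centroid_lon = mean(fixes$lon[idx]),
        member_idx = list(idx)
      )
    }
  }
  if (length(rows) == 0) empty else dplyr::bind_rows(rows)
}

overlap_minutes <- function(s1, e1, s2, e2) {
  as.numeric(difftime(pmin(e1, e2), pmax(s1, s2), units = "mins"))
}

#' Match feeding clusters to GPS clusters
#'
#' For each feeding cluster, the candidate GPS clusters are those
#' overlapping it in time. A single candidate matches directly. Several
#' candidates are merged into one when all pairwise centroid distances
#' are below `centroid_merge_m`; otherwise the candidate with the largest
#' time overlap wins. Feeding clusters without any candidate are emitted
#' to the unmatched report — flagged for manual review, never silently
#' dropped. Matched events get their boundaries corrected against the GPS
#' cluster span (see [correct_boundaries()]).
#'
#' @param fclusters Feeding clusters ([find_feeding_clusters()]).
#' @param gclusters GPS clusters ([find_gps_clusters()]), same animal.
#' @param fixes The animal's GPS fixes (used to recompute merged
#'   centroids).
#' @param fix_interval_min GPS fix interval (minutes) of this animal's
#'   schedule, used for boundary correction.
#' @param cfg A [detection_config()].
#' @return A list with `events` (tibble: `animal_id`, `start`, `end`,
#'   `duration_min`, `gps_start`, `gps_end`, `gps_duration_min`,
#'   `centroid_lat`, `centroid_lon`, `n_gps_merged`, `start_corrected`,
#'   `end_corrected`, `match_status`) and `unmatched` (feeding clusters
#'   with no GPS overlap).
#' @export
match_feeding_to_gps <- function(fclusters, gclusters, fixes,
                                 fix_interval_min,
                                 cfg = detection_config()) {
  events <- list()
  unmatched <- list()
  for (i in seq_len(nrow(fclusters))) {
    fc <- fclusters[i, ]
    ov <- if (nrow(gclusters) > 0) {
      overlap_minutes(fc$start, fc$end, gclusters$start, gclusters$end)
    } else numeric(0)
    cand <- which(ov > 0)
    if (length(cand) == 0) {
      unmatched[[length(unmatched) + 1L]] <- fc
      next
    }
    if (length(cand) == 1) {
      g <- gclusters[cand, ]
      merged_n <- 1L
    } else {
      cl <- gclusters[cand, ]
      pair_d <- outer(seq_len(nrow(cl)), seq_len(nrow(cl)), function(a, b) {
        haversine_m(cl$centroid_lat[a], cl$centroid_lon[a],
                    cl$centroid_lat[b], cl$centroid_lon[b])
      })
      if (all(pair_d[upper.tri(pair_d)] < cfg$centroid_merge_m)) {
        idx <- sort(unique(unlist(cl$member_idx)))
        g <- tibble(
          animal_id = cl$animal_id[1],
          start = min(cl$start), end = max(cl$end),
          n_fixes = length(idx),
          centroid_lat = mean(fixes$lat[idx]),
          centroid_lon = mean(fixes$lon[idx]),
          member_idx = list(idx)
        )
        merged_n <- nrow(cl)
      } else {
        g <- cl[which.max(ov[cand]), ]
        merged_n <- 1L
      }
    }
    ev <- correct_boundaries(
      start = fc$start, end = fc$end,
      gps_start = g$start, gps_end = g$end,
      fix_interval_min = fix_interval_min
    )
    events[[length(events) + 1L]] <- tibble(
      animal_id = fc$animal_id,
      start = ev$start, end = ev$end,
      duration_min = interval_minutes(ev$start, ev$end),
      gps_start = g$start, gps_end = g$end,
      gps_duration_min = interval_minutes(g$start, g$end),
      centroid_lat = g$centroid_lat, centroid_lon = g$centroid_lon,
      n_gps_merged = merged_n,
      start_corrected = ev$start_corrected,
      end_corrected = ev$end_corrected,
      match_status = if (merged_n > 1) "merged" else "matched"
    )
  }
  list(
    events = if (length(events) > 0) dplyr::bind_rows(events) else
      tibble(animal_id = character(), start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"), duration_min = integer(),
             gps_start = as.POSIXct(character(), tz = "UTC"),
             gps_end = as.POSIXct(character(), tz = "UTC"),
             gps_duration_min = integer(), centroid_lat = double(),
             centroid_lon = double(), n_gps_merged = integer(),
             start_corrected = logical(), end_corrected = logical(),
             match_status = character()),
    unmatched = if (length(unmatched) > 0) dplyr::bind_rows(unmatched) else
      fclusters[0, ]
  )
}

#' Clamp feeding-cluster boundaries to the GPS cluster span
#'
#' A feeding cluster should not start more than one GPS fix interval
#' before the animal was stationary, nor end more than one interval after.
#' When it does, the boundary is pulled to `gps_start - interval` (or
#' `gps_end + interval`); boundaries within the tolerance are untouched.
#'
#' @param start,end Feeding-cluster boundaries (POSIXct).
#' @param gps_start,gps_end Matched GPS-cluster boundaries.
#' @param fix_interval_min Fix interval in minutes (3 or 15 by schedule).
#' @return A list `start`, `end`, `start_corrected`, `end_corrected`.
#' @export
correct_boundaries <- function(start, end, gps_start, gps_end,
                               fix_interval_min) {
  fi <- mins(fix_interval_min)
  start_corrected <- start < gps_start - fi
  if (start_corrected) start <- gps_start - fi
  end_corrected <- end > gps_end + fi
  if (end_corrected) end <- gps_end + fi
  list(start = start, end = end,
       start_corrected = start_corrected, end_corrected = end_corrected)
}

#' Scan for high-ACC-variation bursts before an event
#'
#' Checks the half-open window `[event_start - pre_event_scan_min,
#' event_start)` for bursts labelled trotting/running (T) by the SVM or
#' either ensemble, the signature of a hunt preceding a kill.
#'
#' @param preds Prediction set covering the pre-event window.
#' @param event_start Event start time (POSIXct).
#' @param cfg A [detection_config()].
#' @return `TRUE` or `FALSE`; a window containing no bursts at all gives
#'   `FALSE` with a warning.
#' @export
scan_high_acc_before <- function(preds, event_start,
                                 cfg = detection_config()) {
  lo <- event_start - mins(cfg$pre_event_scan_min)
  sel <- preds$start_time >= lo & preds$start_time < event_start
  if (!any(sel)) {
    warning("no bursts in the pre-event scan window")
    return(FALSE)
  }
  any(high_acc_burst(preds[sel, ]))
}

#' Whole minutes between two times
#'
#' Floor of the elapsed seconds divided by 60, as used for reported event
#' durations.
#'
#' @param start,end POSIXct times with `end >= start`.
#' @return Integer minutes.
#' @examples
#' interval_minutes(as.POSIXct("2015-02-07 19:03", tz = "UTC"),
#'                  as.POSIXct("2015-02-07 22:06", tz = "UTC"))  # 183
#' @export
interval_minutes <- function(start, end) {
  secs <- as.numeric(difftime(end, start, units = "secs"))
  if (any(secs < 0)) stop("end is before start")
  as.integer(floor(secs / 60))
}

#' Resting and walking clusters
#'
#' A re-designed, optional complement to feeding events (disabled by
#' default in the pipeline): a resting cluster is a GPS cluster that is
#' not part of any feeding event and whose overlapping bursts are majority
#' resting (R, by the mean-ensemble label); a walking cluster is a maximal
#' run of majority-walking (W) bursts lasting at least `walk_run_min`
#' minutes with no GPS cluster overlapping it, its centroid the mean of
#' the along-route fixes.
#'
#' @param preds Prediction set for one animal.
#' @param fixes The animal's GPS fixes.
#' @param events Detected feeding events for the animal (may be empty).
#' @param cfg A [detection_config()].
#' @return A tibble: `type` ("resting"/"walking"), `start`, `end`,
#'   `centroid_lat`, `centroid_lon`.
#' @export
resting_walking_clusters <- function(preds, fixes, events,
                                     cfg = detection_config()) {
  out <- list()
  gcl <- find_gps_clusters(fixes, cfg)
  for (i in seq_len(nrow(gcl))) {
    g <- gcl[i, ]
    in_event <- nrow(events) > 0 &&
      any(overlap_minutes(g$start, g$end, events$start, events$end) > 0)
    if (in_event) next
    sel <- preds$start_time >= g$start & preds$start_time <= g$end
    if (!any(sel)) next
    if (mean(preds$mean_label[sel] == "R") > 0.5) {
      out[[length(out) + 1L]] <- tibble(
        type = "resting", start = g$start, end = g$end,
        centroid_lat = g$centroid_lat, centroid_lon = g$centroid_lon
      )
    }
  }
  # walking: maximal runs of majority-W bursts with no GPS-cluster overlap
  is_w <- preds$mean_label == "W"
  runs <- rle(is_w)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    s <- preds$start_time[starts[r]]
    e <- preds$start_time[ends[r]]
    if (difftime(e, s, units = "mins") < cfg$walk_run_min) next
    if (nrow(gcl) > 0 && any(overlap_minutes(s, e, gcl$start, gcl$end) > 0)) next
    sel <- fixes$time >= s & fixes$time <= e
    out[[length(out) + 1L]] <- tibble(
      type = "walking", start = s, end = e,
      centroid_lat = if (any(sel)) mean(fixes$lat[sel]) else NA_real_,
      centroid_lon = if (any(sel)) mean(fixes$lon[sel]) else NA_real_
    )
  }
  if (length(out) == 0) {
    tibble(type = character(), start = as.POSIXct(character(), tz = "UTC"),
           end = as.POSIXct(character(), tz = "UTC"),
           centroid_lat = double(), centroid_lon = double())
  } else dplyr::bind_rows(out)
}

#' Suggest shared kill sites across animals
#'
#' Coalition members feed together; events of two animals overlapping in
#' time with centroids less than `centroid_merge_m` apart are suggested as
#' one shared site. Reported as suggestions only — events themselves stay
#' per animal.
#'
#' @param events Event tibble covering several animals.
#' @param cfg A [detection_config()].
#' @return A tibble of suggested pairs: `animal_a`, `start_a`, `animal_b`,
#'   `start_b`, `centroid_dist_m`.
#' @export
suggest_shared_sites <- function(events, cfg = detection_config()) {
  out <- list()
  n <- nrow(events)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (events$animal_id[i] == events$animal_id[j]) next
        if (overlap_minutes(events$start[i], events$end[i],
                            events$start[j], events$end[j]) <= 0) next
        d <- haversine_m(events$centroid_lat[i], events$centroid_lon[i],
                         events$centroid_lat[j], events$centroid_lon[j])
        if (d < cfg$centroid_merge_m) {
          out[[length(out) + 1L]] <- tibble(
            animal_a = events$animal_id[i], start_a = events$start[i],
            animal_b = events$animal_id[j], start_b = events$start[j],
            centroid_dist_m = d
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    tibble(animal_a = character(), start_a = as.POSIXct(character(), tz = "UTC"),
           animal_b = character(), start_b = as.POSIXct(character(), tz = "UTC"),
           centroid_dist_m = double())
  } else dplyr::bind_rows(out)
}
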