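NC <- not_conclusive_label()
t0 <- utc("2015-02-07 12:00:00")

test_that("true feeding is the SVM-or-ensemble disjunction", {
  p <- fake_preds(t0 + (0:2) * 120,
                  svm = c("F", NC, "R"),
                  mean_ = c("R", NC, "R"),
                  majority = c("R", NC, "R"))
  expect_equal(true_feeding(p), c(TRUE, FALSE, FALSE))
  # an F from a non-designated algorithm alone does not count
  p$lda_label <- "F"
  expect_equal(true_feeding(p), c(TRUE, FALSE, FALSE))
  p2 <- fake_preds(t0, svm = "R", mean_ = "F", majority = "R")
  expect_true(true_feeding(p2))
})

test_that("a dense feeding block forms exactly one trimmed cluster", {
  # 20 true-feeding bursts at 2-min spacing (38 min), padding around them
  times <- t0 + (0:59) * 120
  svm <- rep("R", 60); svm[21:40] <- "F"
  p <- fake_preds(times, svm = svm, mean_ = "R", majority = "R")
  cl <- find_feeding_clusters(p)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start, times[21])
  expect_equal(cl$end, times[40])
  expect_equal(cl$n_true_feeding, 20L)
})

test_that("short feeding bouts fall to the 30-min duration filter", {
  times <- t0 + (0:39) * 120
  svm <- rep("R", 40); svm[11:20] <- "F"  # 18-min span
  p <- fake_preds(times, svm = svm, mean_ = "R", majority = "R")
  expect_equal(nrow(find_feeding_clusters(p)), 0)
})

test_that("the 120-min gap rule decides merging of dense blocks", {
  mk <- function(gap_min) {
    n1 <- 20
    b2_start <- n1 + gap_min / 2  # bursts every 2 min
    times <- t0 + (0:(b2_start + 25)) * 120
    svm <- rep("R", length(times))
    svm[1:n1] <- "F"
    svm[(b2_start + 1):(b2_start + 20)] <- "F"
    find_feeding_clusters(fake_preds(times, svm = svm, mean_ = "R",
                                     majority = "R"))
  }
  expect_equal(nrow(mk(100)), 1)
  expect_equal(nrow(mk(130)), 2)
})

test_that("GPS chaining respects the 50-m and 30-min rules", {
  # 12 fixes at 3-min spacing inside a 10-m circle -> one cluster
  th <- seq(0, 2 * pi, length.out = 12)
  lat0 <- -22.58; lon0 <- 18.19
  f <- tibble::tibble(
    animal_id = "M1", time = t0 + (0:11) * 180,
    lat = lat0 + 5e-5 * sin(th), lon = lon0 + 5e-5 * cos(th)
  )
  cl <- find_gps_clusters(f)
  expect_equal(nrow(cl), 1)
  expect_lt(brute_haversine(cl$centroid_lat, cl$centroid_lon, lat0, lon0), 10)

  # 9 fixes (24 min) -> too short
  expect_equal(nrow(find_gps_clusters(f[1:9, ])), 0)
})

test_that("stop-transit-stop tracks split into the right clusters", {
  set.seed(77)
  stop1 <- tibble::tibble(
    animal_id = "M1", time = t0 + (0:15) * 180,
    lat = -22.58 + runif(16, -5e-5, 5e-5), lon = 18.19 + runif(16, -5e-5, 5e-5)
  )
  transit <- tibble::tibble(
    animal_id = "M1", time = t0 + 16 * 180 + (0:3) * 180,
    lat = -22.58 - (1:4) * 0.004, lon = 18.19
  )
  stop2 <- tibble::tibble(
    animal_id = "M1", time = max(transit$time) + (1:21) * 180,
    lat = -22.60 + runif(21, -5e-5, 5e-5), lon = 18.19 + runif(21, -5e-5, 5e-5)
  )
  f <- dplyr::bind_rows(stop1, transit, stop2)
  cl <- find_gps_clusters(f)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$n_fixes, c(16L, 21L))
  oracle <- brute_gps_clusters(f$lat, f$lon, f$time)
  expect_equal(length(oracle), 2)
  expect_equal(cl$member_idx[[1]], oracle[[1]])
  expect_equal(cl$member_idx[[2]], oracle[[2]])
})

test_that("haversine distance is exact at the equator and symmetric", {
  expect_equal(haversine_m(0, 0, 0, 0), 0)
  # closed form: arc length R * dlon at the equator
  expected <- 6371008.8 * 0.001 * pi / 180
  expect_equal(haversine_m(0, 0, 0, 0.001), expected, tolerance = 1e-6)
  set.seed(71)
  for (i in 1:20) {
    a <- c(runif(1, -80, 80), runif(1, -179, 179))
    b <- c(runif(1, -80, 80), runif(1, -179, 179))
    d1 <- haversine_m(a[1], a[2], b[1], b[2])
    d2 <- haversine_m(b[1], b[2], a[1], a[2])
    expect_equal(d1, d2, tolerance = 1e-9)
    expect_equal(d1, brute_haversine(a[1], a[2], b[1], b[2]),
                 tolerance = 1e-6)
  }
})

test_that("matching picks overlap, merges close centroids, reports unmatched", {
  fcl <- tibble::tibble(
    animal_id = "M1", start = t0, end = t0 + 3600,
    n_bursts = 30L, n_true_feeding = 20L,
    member_times = list(t0 + (0:29) * 120)
  )
  mk_fix <- function(n, t_start, lat) tibble::tibble(
    animal_id = "M1", time = t_start + (0:(n - 1)) * 180,
    lat = lat, lon = 18.19
  )
  # single overlapping cluster
  fixes <- mk_fix(20, t0, -22.58)
  gcl <- find_gps_clusters(fixes)
  m <- match_feeding_to_gps(fcl, gcl, fixes, fix_interval_min = 3)
  expect_equal(nrow(m$events), 1)
  expect_equal(m$events$match_status, "matched")

  # two overlapping clusters with centroids ~30 m apart -> merged
  f1 <- mk_fix(12, t0, -22.58)
  f2 <- mk_fix(12, t0 + 2400, -22.58 + 30 / 111194.9)
  # separate the chains with one far fix between them
  far <- tibble::tibble(animal_id = "M1", time = t0 + 2340,
                        lat = -22.6, lon = 18.19)
  fixes <- dplyr::bind_rows(f1, far, f2)
  gcl <- find_gps_clusters(fixes)
  expect_equal(nrow(gcl), 2)
  m <- match_feeding_to_gps(fcl, gcl, fixes, fix_interval_min = 3)
  expect_equal(nrow(m$events), 1)
  expect_equal(m$events$match_status, "merged")
  expect_equal(m$events$n_gps_merged, 2L)

  # no temporal overlap -> unmatched report, never dropped silently
  fixes <- mk_fix(20, t0 + 86400, -22.58)
  gcl <- find_gps_clusters(fixes)
  m <- match_feeding_to_gps(fcl, gcl, fixes, fix_interval_min = 3)
  expect_equal(nrow(m$events), 0)
  expect_equal(nrow(m$unmatched), 1)
})

test_that("boundary correction clamps to the GPS span plus one fix interval", {
  ev <- correct_boundaries(
    start = utc("2015-02-07 19:00:00"), end = utc("2015-02-07 21:00:00"),
    gps_start = utc("2015-02-07 19:10:00"), gps_end = utc("2015-02-07 21:05:00"),
    fix_interval_min = 3
  )
  expect_equal(ev$start, utc("2015-02-07 19:07:00"))
  expect_true(ev$start_corrected)
  expect_equal(ev$end, utc("2015-02-07 21:00:00"))
  expect_false(ev$end_corrected)

  # feeding inside the GPS span: untouched
  ev <- correct_boundaries(utc("2015-02-07 19:15:00"), utc("2015-02-07 20:00:00"),
                           utc("2015-02-07 19:10:00"), utc("2015-02-07 21:05:00"),
                           fix_interval_min = 3)
  expect_false(ev$start_corrected || ev$end_corrected)

  # 10 min early is within a 15-min fix interval: untouched
  ev <- correct_boundaries(utc("2015-02-07 19:00:00"), utc("2015-02-07 21:00:00"),
                           utc("2015-02-07 19:10:00"), utc("2015-02-07 21:00:00"),
                           fix_interval_min = 15)
  expect_false(ev$start_corrected)
})

test_that("the pre-event scan finds trotting bursts in a half-open hour", {
  ev_start <- t0 + 7200
  times <- t0 + (0:60) * 120
  svm <- rep("R", 61)
  p <- fake_preds(times, svm = svm, mean_ = "R", majority = "R")
  expect_false(scan_high_acc_before(p, ev_start))
  # one T burst 20 min before the start
  svm[times == ev_start - 1200] <- "T"
  p <- fake_preds(times, svm = svm, mean_ = "R", majority = "R")
  expect_true(scan_high_acc_before(p, ev_start))
  # a T burst exactly at the start is outside the half-open window
  svm <- rep("R", 61); svm[times == ev_start] <- "T"
  p <- fake_preds(times, svm = svm, mean_ = "R", majority = "R")
  expect_false(scan_high_acc_before(p, ev_start))
  # empty window warns and returns FALSE
  expect_warning(
    got <- scan_high_acc_before(p[p$start_time > ev_start, ], ev_start),
    "no bursts"
  )
  expect_false(got)
})

test_that("interval_minutes floors elapsed time and rejects reversals", {
  expect_equal(interval_minutes(utc("2015-02-07 19:03:00"),
                                utc("2015-02-07 22:06:00")), 183L)
  expect_equal(interval_minutes(utc("2015-02-07 19:28:00"),
                                utc("2015-02-07 21:08:00")), 100L)
  expect_equal(interval_minutes(t0, t0), 0L)
  expect_equal(interval_minutes(t0, t0 + 119), 1L)
  expect_error(interval_minutes(t0, t0 - 1), "before start")
})

test_that("emitted feeding clusters never overlap in time", {
  set.seed(81)
  for (rep in 1:10) {
    n <- 150
    times <- t0 + cumsum(sample(c(120, 240), n, replace = TRUE))
    svm <- ifelse(runif(n) < 0.35, "F", "R")
    cl <- find_feeding_clusters(fake_preds(times, svm = svm, mean_ = "R",
                                           majority = "R"))
    if (nrow(cl) > 1) {
      expect_true(all(cl$start[-1] > cl$end[-nrow(cl)]))
    }
  }
})

test_that("resting and walking clusters follow the exclusion rules", {
  # stationary cluster + all-R predictions -> one resting cluster
  times <- t0 + (0:30) * 120
  p <- fake_preds(times, svm = "R", mean_ = "R", majority = "R")
  fixes <- tibble::tibble(animal_id = "M1", time = t0 + (0:20) * 180,
                          lat = -22.58, lon = 18.19)
  no_events <- tibble::tibble(start = utc(character()), end = utc(character()))
  rw <- resting_walking_clusters(p, fixes, no_events)
  expect_equal(rw$type, "resting")

  # moving track + all-W predictions -> one walking cluster, no GPS cluster
  pw <- fake_preds(times, svm = "W", mean_ = "W", majority = "W")
  moving <- tibble::tibble(animal_id = "M1", time = t0 + (0:20) * 180,
                           lat = -22.58 - (0:20) * 0.002, lon = 18.19)
  rw <- resting_walking_clusters(pw, moving, no_events)
  expect_equal(rw$type, "walking")

  # a stationary cluster overlapping a feeding event is not resting
  events <- tibble::tibble(start = t0, end = t0 + 3600)
  rw <- resting_walking_clusters(p, fixes, events)
  expect_equal(nrow(rw[rw$type == "resting", ]), 0)
})

test_that("coalition events at one site are suggested as shared", {
  ev <- tibble::tibble(
    animal_id = c("M1", "M2"),
    start = c(t0, t0 + 600), end = c(t0 + 5400, t0 + 4800),
    centroid_lat = c(-22.58, -22.58001), centroid_lon = c(18.19, 18.19)
  )
  s <- suggest_shared_sites(ev)
  expect_equal(nrow(s), 1)
  expect_lt(s$centroid_dist_m, 50)
  # same times, far apart -> no suggestion
  ev$centroid_lat[2] <- -22.6
  expect_equal(nrow(suggest_shared_sites(ev)), 0)
})
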