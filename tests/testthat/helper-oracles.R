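# Independent brute-force oracles. Deliberately naive: explicit sums and
# double loops, no shared code with the package internals.

# All six burst predictors from first principles (explicit DFT).
brute_features <- function(x) {
  n <- length(x)
  mnz <- sum(x) / n
  m2 <- sum((x - mnz)^2) / n
  m3 <- sum((x - mnz)^3) / n
  m4 <- sum((x - mnz)^4) / n
  sdz <- sqrt(m2)
  q <- if (n %% 2 == 0) n / 2 else (n - 1) / 2
  w <- ord <- numeric(q)
  xc <- x - mnz
  for (j in 1:q) {
    w[j] <- 2 * pi * j / n
    re <- im <- 0
    for (t in 1:n) {
      re <- re + xc[t] * cos(w[j] * (t - 1))
      im <- im - xc[t] * sin(w[j] * (t - 1))
    }
    ord[j] <- (re^2 + im^2) / n
  }
  wmz <- if (sum(ord) > 0) sum(w * ord) / sum(ord) else 0
  list(mnz = mnz, sdz = sdz, wmz = wmz,
       icvz = if (sdz > 0) mnz / sdz else NA_real_,
       kz = if (m2 > 0) m4 / m2^2 else 0,
       sz = if (m2 > 0) m3 / m2^1.5 else 0,
       periodogram = list(frequencies = w, ordinates = ord))
}

# Haversine from the textbook formula (no geosphere).
brute_haversine <- function(lat1, lon1, lat2, lon2, r = 6371008.8) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Feeding clusters by explicit enumeration of every window and merge
# decision. times: POSIXct; tf: logical true-feeding flags.
brute_feeding_clusters <- function(times, tf, window_min = 30,
                                   fraction = 1 / 3, min_cluster_min = 30,
                                   max_gap_min = 120) {
  n <- length(times)
  covered <- rep(FALSE, n)
  for (i in 1:n) {
    in_win <- which(times >= times[i] &
                    times < times[i] + as.difftime(window_min, units = "mins"))
    if (sum(tf[in_win]) >= ceiling(fraction * length(in_win))) {
      covered[in_win] <- TRUE
    }
  }
  # contiguous covered runs -> trim to true-feeding members
  cand <- list()
  i <- 1
  while (i <= n) {
    if (covered[i]) {
      j <- i
      while (j < n && covered[j + 1]) j <- j + 1
      members <- i:j
      tf_members <- members[tf[members]]
      if (length(tf_members) > 0) {
        cand[[length(cand) + 1]] <- c(min(tf_members), max(tf_members))
      }
      i <- j + 1
    } else i <- i + 1
  }
  # merge pairs until fixpoint
  repeat {
    merged_any <- FALSE
    if (length(cand) >= 2) {
      for (k in 1:(length(cand) - 1)) {
        gap <- difftime(times[cand[[k + 1]][1]], times[cand[[k]][2]],
                        units = "mins")
        if (as.numeric(gap) <= max_gap_min) {
          cand[[k]] <- c(cand[[k]][1], cand[[k + 1]][2])
          cand[[k + 1]] <- NULL
          merged_any <- TRUE
          break
        }
      }
    }
    if (!merged_any) break
  }
  keep <- list()
  for (c_ in cand) {
    dur <- as.numeric(difftime(times[c_[2]], times[c_[1]], units = "mins"))
    if (dur >= min_cluster_min) keep[[length(keep) + 1]] <- c_
  }
  keep
}

# GPS clusters by a plain loop with the textbook haversine.
brute_gps_clusters <- function(lat, lon, times, dist_m = 50,
                               min_duration_min = 30) {
  n <- length(times)
  clusters <- list()
  cur <- c(1)
  for (i in seq_len(n - 1)) {
    d <- brute_haversine(lat[i], lon[i], lat[i + 1], lon[i + 1])
    if (d <= dist_m) {
      cur <- c(cur, i + 1)
    } else {
      clusters[[length(clusters) + 1]] <- cur
      cur <- c(i + 1)
    }
  }
  clusters[[length(clusters) + 1]] <- cur
  keep <- list()
  for (cl in clusters) {
    dur <- as.numeric(difftime(times[max(cl)], times[min(cl)],
                               units = "mins"))
    if (dur >= min_duration_min) keep[[length(keep) + 1]] <- cl
  }
  keep
}
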