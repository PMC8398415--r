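#' Per-behaviour synthetic signal models
#'
#' Frequency-domain caricatures of the six behaviours on the heave (z)
#' axis, not biomechanical models: each behaviour is a baseline offset
#' plus an optional sinusoid plus Gaussian noise; feeding adds Poisson
#' head-jerk spikes with exponentially distributed amplitudes. Defaults:
#' resting R (offset 1.0, noise sd 0.02), walking W (1.5 Hz sinusoid,
#' amplitude 0.3, noise 0.05), trotting/running T (3.5 Hz, amplitude 0.8,
#' noise 0.1), feeding F (noise 0.08 plus spikes at 0.5/s with
#' Exp(mean 0.6) amplitudes), grooming G (0.5 Hz, amplitude 0.15, noise
#' 0.06), drinking D (2 Hz, amplitude 0.1, offset 0.8, noise 0.04). These
#' are chosen so the six burst predictors separate the classes.
#'
#' @param amp_scale Multiplier on all oscillation/spike amplitudes and
#'   offsets (used to simulate an individual with a shifted signal
#'   distribution).
#' @param noise_scale Multiplier on all noise standard deviations.
#' @return Named list (by behaviour code) of model parameter lists with
#'   fields `offset`, `noise_sd`, `freq_hz`, `amp`, `spike_rate`,
#'   `spike_amp_mean`.
#' @export
behaviour_models <- function(amp_scale = 1, noise_scale = 1) {
  m <- list(
    D = list(offset = 0.8, noise_sd = 0.04, freq_hz = 2.0, amp = 0.10,
             spike_rate = 0, spike_amp_mean = 0),
    F = list(offset = 0.0, noise_sd = 0.08, freq_hz = 0, amp = 0,
             spike_rate = 0.5, spike_amp_mean = 0.6),
    G = list(offset = 0.0, noise_sd = 0.06, freq_hz = 0.5, amp = 0.15,
             spike_rate = 0, spike_amp_mean = 0),
    R = list(offset = 1.0, noise_sd = 0.02, freq_hz = 0, amp = 0,
             spike_rate = 0, spike_amp_mean = 0),
    T = list(offset = 0.0, noise_sd = 0.10, freq_hz = 3.5, amp = 0.80,
             spike_rate = 0, spike_amp_mean = 0),
    W = list(offset = 0.0, noise_sd = 0.05, freq_hz = 1.5, amp = 0.30,
             spike_rate = 0, spike_amp_mean = 0)
  )
  lapply(m, function(p) {
    p$offset <- p$offset * amp_scale
    p$amp <- p$amp * amp_scale
    p$spike_amp_mean <- p$spike_amp_mean * amp_scale
    p$noise_sd <- p$noise_sd * noise_scale
    p
  })
}

# One burst of synthetic z-axis samples. Consumes the current RNG stream.
simulate_burst_samples <- function(behaviour, n, rate, models) {
  p <- models[[behaviour]]
  if (p$freq_hz >= rate / 2) {
    stop(sprintf("oscillation %.3g Hz at/above Nyquist for %.3g Hz sampling",
                 p$freq_hz, rate))
  }
  tt <- (seq_len(n) - 1L) / rate
  y <- p$offset + rnorm(n, 0, p$noise_sd)
  if (p$amp > 0) {
    y <- y + p$amp * sin(2 * pi * p$freq_hz * tt + runif(1, 0, 2 * pi))
  }
  if (p$spike_rate > 0) {
    n_spikes <- rpois(1, p$spike_rate * n / rate)
    if (n_spikes > 0) {
      pos <- sample.int(n, min(n_spikes, n))
      y[pos] <- y[pos] + rexp(length(pos), rate = 1 / p$spike_amp_mean)
    }
  }
  y
}

#' Scenario configuration for the simulator
#'
#' A scenario is a set of animals, each with a collar configuration, a GPS
#' schedule, optionally animal-specific signal models, and a shared or
#' per-animal timeline of non-overlapping labelled behaviour episodes.
#' Episodes carry a location: the spot for stationary behaviours (R, F, G,
#' D) or the destination for moving ones (W, T); moving episodes travel in
#' a straight line from the previous location.
#'
#' @param animals Named list: for each animal id a list with `config`
#'   ([collar_config()]), `gps_active_min` (active fix interval, 3 or 15),
#'   `gps_inactive_min` (default 360), and optionally `models`
#'   ([behaviour_models()]).
#' @param episodes Tibble `animal_id`, `behaviour`, `start`, `end`
#'   (POSIXct UTC), `lat`, `lon`; non-overlapping per animal.
#' @param seed Integer master seed; per-animal substreams are derived from
#'   it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(animals, episodes, seed = 1) {
  stopifnot(is.list(animals), length(names(animals)) == length(animals))
  for (a in names(animals)) {
    ep <- episodes[episodes$animal_id == a, ]
    ep <- ep[order(ep$start), ]
    if (nrow(ep) > 1 && any(ep$start[-1] < ep$end[-nrow(ep)])) {
      stop("overlapping episodes for animal ", a)
    }
  }
  structure(list(animals = animals, episodes = episodes, seed = seed),
            class = "scenario_config")
}

# Derived per-animal seed so streams are independent yet reproducible and
# stay well inside 32-bit integer range.
animal_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 1000 + idx * 7919) %% 2147483647)
}

#' Generate labelled accelerometer bursts for a scenario
#'
#' Emits one burst every `burst_interval` seconds per animal, from the
#' first episode start to the last episode end, labelled by the episode
#' the burst start falls in (bursts outside every episode are not
#' emitted). Samples are drawn from the per-behaviour signal models.
#' Deterministic given the scenario seed.
#'
#' @param scenario A [scenario_config()].
#' @return A list with `bursts` (tibble as [acc_bursts()]) and `truth`
#'   (list: `burst_labels` tibble and the scenario `episodes`).
#' @export
generate_bursts <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  all_bursts <- list()
  for (idx in seq_along(scenario$animals)) {
    a <- names(scenario$animals)[idx]
    an <- scenario$animals[[a]]
    cfg <- an$config
    models <- an$models %||% behaviour_models()
    ep <- scenario$episodes[scenario$episodes$animal_id == a, ]
    ep <- ep[order(ep$start), ]
    if (nrow(ep) == 0) next
    times <- seq(min(ep$start), max(ep$end), by = cfg$burst_interval)
    ep_of <- find_episode(times, ep)
    keep <- !is.na(ep_of)
    times <- times[keep]
    ep_of <- ep_of[keep]
    set.seed(animal_seed(scenario$seed, idx))
    samples <- vector("list", length(times))
    for (i in seq_along(times)) {
      samples[[i]] <- simulate_burst_samples(
        ep$behaviour[ep_of[i]], cfg$samples_per_burst, cfg$sampling_rate,
        models
      )
    }
    all_bursts[[a]] <- acc_bursts(
      animal_id = a, start_time = times, sampling_rate = cfg$sampling_rate,
      samples = samples, label = ep$behaviour[ep_of],
      firmware = cfg$firmware
    )
  }
  bursts <- dplyr::bind_rows(all_bursts)
  list(
    bursts = bursts,
    truth = list(
      burst_labels = bursts[, c("animal_id", "start_time", "label")],
      episodes = scenario$episodes
    )
  )
}

# Index of the episode containing each time (start inclusive, end
# exclusive except the final episode end), NA when none.
find_episode <- function(times, ep) {
  out <- rep(NA_integer_, length(times))
  for (j in seq_len(nrow(ep))) {
    hit <- times >= ep$start[j] & times < ep$end[j]
    out[hit] <- j
  }
  out
}

#' Generate a GPS track for a scenario
#'
#' Emits fixes per episode following the ACC-informed schedule: active
#' behaviours (everything except resting) produce fixes at the animal's
#' active interval, resting produces fixes at the 6-h inactive interval.
#' Stationary episodes jitter fixes uniformly within 10 m of the episode
#' location; moving episodes (W, T) interpolate linearly from the previous
#' location to the episode destination. Deterministic given the scenario
#' seed.
#'
#' @param scenario A [scenario_config()].
#' @return A list with `fixes` (tibble `animal_id`, `time`, `lat`, `lon`)
#'   and `truth` (the scenario episodes).
#' @export
generate_track <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  moving <- c("W", "T")
  rows <- list()
  for (idx in seq_along(scenario$animals)) {
    a <- names(scenario$animals)[idx]
    an <- scenario$animals[[a]]
    active_s <- (an$gps_active_min %||% 15) * 60
    inactive_s <- (an$gps_inactive_min %||% 360) * 60
    ep <- scenario$episodes[scenario$episodes$animal_id == a, ]
    ep <- ep[order(ep$start), ]
    if (nrow(ep) == 0) next
    set.seed(animal_seed(scenario$seed, idx) + 1L)
    pos <- c(ep$lat[1], ep$lon[1])
    for (j in seq_len(nrow(ep))) {
      interval <- if (ep$behaviour[j] == "R") inactive_s else active_s
      t_fix <- seq(ep$start[j], ep$end[j], by = interval)
      t_fix <- t_fix[t_fix < ep$end[j]]
      if (length(t_fix) == 0) {
        if (ep$behaviour[j] %in% moving) pos <- c(ep$lat[j], ep$lon[j])
        next
      }
      if (ep$behaviour[j] %in% moving) {
        frac <- as.numeric(difftime(t_fix, ep$start[j], units = "secs")) /
          as.numeric(difftime(ep$end[j], ep$start[j], units = "secs"))
        lat <- pos[1] + frac * (ep$lat[j] - pos[1])
        lon <- pos[2] + frac * (ep$lon[j] - pos[2])
        pos <- c(ep$lat[j], ep$lon[j])
      } else {
        jit <- jitter_m(length(t_fix), max_m = 10, at_lat = ep$lat[j])
        lat <- ep$lat[j] + jit$dlat
        lon <- ep$lon[j] + jit$dlon
        pos <- c(ep$lat[j], ep$lon[j])
      }
      rows[[length(rows) + 1L]] <- tibble(
        animal_id = a, time = t_fix, lat = lat, lon = lon
      )
    }
  }
  fixes <- dplyr::bind_rows(rows)
  fixes <- fixes[order(fixes$animal_id, fixes$time), ]
  list(fixes = fixes, truth = list(episodes = scenario$episodes))
}

# Uniform jitter within a disc of max_m metres, converted to degrees.
jitter_m <- function(n, max_m, at_lat) {
  r <- max_m * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  m_per_deg_lat <- pi * EARTH_RADIUS_M / 180
  m_per_deg_lon <- m_per_deg_lat * cos(at_lat * pi / 180)
  list(dlat = r * sin(th) / m_per_deg_lat,
       dlon = r * cos(th) / m_per_deg_lon)
}

#' Canonical free-ranging study scenario
#'
#' Two coalition animals sharing one 21-day timeline in the free-ranging
#' regime (10 Hz, 3.6-s bursts every 120 s): nine feeding episodes of
#' 60-150 min at distinct kill sites, six of them immediately preceded by
#' a trotting/running chase, daily walking transits, midday grooming and
#' drinking bouts, and resting otherwise. One animal carries the 3-min GPS
#' schedule, the other the 15-min schedule; both fall back to 6-h fixes
#' when resting. Episode boundaries sit on the 2-min burst grid so ground
#' truth is exact.
#'
#' @param seed Master seed for the scenario.
#' @return A [scenario_config()] whose episode table carries an extra
#'   attribute `feeding_truth`: tibble of the nine feeding episodes with
#'   `start`, `end`, `lat`, `lon`, and `chase_before`.
#' @export
make_study_scenario <- function(seed = 1) {
  t0 <- as.POSIXct("2015-02-06 00:00:00", tz = "UTC")
  base_lat <- -22.58
  base_lon <- 18.19
  feeding_days <- c(1, 3, 5, 8, 10, 12, 15, 17, 20)
  feeding_dur_min <- c(90, 120, 60, 150, 76, 100, 136, 60, 110)
  chase_before <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)

  ep <- list()
  feeding_truth <- list()
  add <- function(behaviour, start_min, end_min, lat, lon, day) {
    ep[[length(ep) + 1L]] <<- tibble(
      behaviour = behaviour,
      start = t0 + (day * 1440 + start_min) * 60,
      end = t0 + (day * 1440 + end_min) * 60,
      lat = lat, lon = lon
    )
  }
  for (day in 0:20) {
    # a fresh overnight location ~2 km from the shared waterhole at base,
    # and a distinct kill site per feeding day; deterministic in the day
    day_lat <- base_lat + 0.018 * sin(day * 1.7)
    day_lon <- base_lon + 0.018 * cos(day * 1.1)
    kill_lat <- day_lat + 0.012 * sin(day * 2.3 + 1)
    kill_lon <- day_lon + 0.012 * cos(day * 0.9 + 2)
    add("R", 0, 360, day_lat, day_lon, day)            # night rest
    add("W", 360, 420, base_lat, base_lon, day)        # transit to waterhole
    add("R", 420, 720, base_lat, base_lon, day)
    add("G", 720, 750, base_lat, base_lon, day)
    add("D", 750, 780, base_lat, base_lon, day)
    add("R", 780, 1020, base_lat, base_lon, day)
    fi <- match(day, feeding_days)
    if (!is.na(fi)) {
      dur <- feeding_dur_min[fi]
      if (chase_before[fi]) {
        # approach to ~550 m short of the kill, then a moving chase
        add("W", 1020, 1070, kill_lat + 0.005, kill_lon, day)
        add("T", 1070, 1080, kill_lat, kill_lon, day)
      } else {
        add("W", 1020, 1080, kill_lat, kill_lon, day)
      }
      add("F", 1080, 1080 + dur, kill_lat, kill_lon, day)
      add("R", 1080 + dur, 1440, kill_lat, kill_lon, day)
      feeding_truth[[length(feeding_truth) + 1L]] <- tibble(
        start = t0 + (day * 1440 + 1080) * 60,
        end = t0 + (day * 1440 + 1080 + dur) * 60,
        lat = kill_lat, lon = kill_lon,
        chase_before = chase_before[fi]
      )
    } else {
      add("W", 1020, 1080, day_lat, day_lon, day)
      add("R", 1080, 1440, day_lat, day_lon, day)
    }
  }
  ep <- dplyr::bind_rows(ep)
  episodes <- dplyr::bind_rows(
    dplyr::mutate(ep, animal_id = "M1", .before = 1),
    dplyr::mutate(ep, animal_id = "M2", .before = 1)
  )
  attr(episodes, "feeding_truth") <- dplyr::bind_rows(feeding_truth)

  free <- collar_preset("free_ranging")
  scenario_config(
    animals = list(
      M1 = list(config = free, gps_active_min = 3, gps_inactive_min = 360),
      M2 = list(config = free, gps_active_min = 15, gps_inactive_min = 360)
    ),
    episodes = episodes,
    seed = seed
  )
}

#' Captive ground-truthing scenario
#'
#' A set of observed "captive" animals in the 30-s burst regime (firmware
#' A, 10 Hz, 4-s bursts) whose timeline cycles through the six behaviours
#' in 5-min episodes until each behaviour has `bursts_per_class` bursts
#' per animal. Used to train and cross-validate the classifier bank.
#'
#' @param seed Master seed.
#' @param n_animals Number of captive animals.
#' @param bursts_per_class Bursts per behaviour per animal (multiple of
#'   10).
#' @param shifted_animal Optional id (e.g. `"C3"`) given amplitude- and
#'   noise-shifted signal models, emulating an individual the model
#'   transfers poorly to.
#' @param amp_scale,noise_scale Shift applied to that animal's models.
#' @return A [scenario_config()].
#' @export
make_captive_scenario <- function(seed = 1, n_animals = 5,
                                  bursts_per_class = 30,
                                  shifted_animal = NULL,
                                  amp_scale = 1.8, noise_scale = 2.5) {
  t0 <- as.POSIXct("2017-10-06 04:00:00", tz = "UTC")
  per_episode <- 10L  # bursts per 5-min episode at the 30-s interval
  cycles <- ceiling(bursts_per_class / per_episode)
  cfg <- collar_preset("captive_10hz")
  lat <- -22.5803; lon <- 18.1875

  eps <- list()
  for (i in seq_len(n_animals)) {
    a <- paste0("C", i)
    k <- 0L
    for (cy in seq_len(cycles)) {
      for (b in BEHAVIOURS) {
        eps[[length(eps) + 1L]] <- tibble(
          animal_id = a, behaviour = b,
          start = t0 + k * 300, end = t0 + (k + 1) * 300,
          lat = lat, lon = lon
        )
        k <- k + 1L
      }
    }
  }
  animals <- setNames(lapply(seq_len(n_animals), function(i) {
    an <- list(config = cfg, gps_active_min = 15, gps_inactive_min = 360)
    if (!is.null(shifted_animal) && paste0("C", i) == shifted_animal) {
      an$models <- behaviour_models(amp_scale = amp_scale,
                                    noise_scale = noise_scale)
    }
    an
  }), paste0("C", seq_len(n_animals)))
  scenario_config(animals, dplyr::bind_rows(eps), seed = seed)
}

#' Write the simulator's ground truth to CSV
#'
#' Dialect: `episode_id,animal_id,behaviour,start,end,lat,lon`, ISO-8601
#' UTC timestamps.
#'
#' @param episodes Episode tibble from a scenario.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(episodes, path) {
  df <- data.frame(
    episode_id = seq_len(nrow(episodes)),
    animal_id = episodes$animal_id,
    behaviour = episodes$behaviour,
    start = format_utc(episodes$start),
    end = format_utc(episodes$end),
    lat = episodes$lat,
    lon = episodes$lon,
    stringsAsFactors = FALSE
  )
  fwrite(df, path, sep = ",", eol = "\n", quote = FALSE)
  invisible(path)
}
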