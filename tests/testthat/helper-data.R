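# Shared fixture builders (all data generated in code).

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A burst tibble with simple deterministic samples.
toy_bursts <- function(n = 3, n_samples = 36, rate = 10, animal = "A1",
                       t0 = utc("2015-02-06 00:00:00"), label = "R",
                       interval = 120) {
  acc_bursts(
    animal_id = animal,
    start_time = t0 + (seq_len(n) - 1) * interval,
    sampling_rate = rate,
    samples = lapply(seq_len(n), function(i) sin(seq_len(n_samples) + i)),
    label = label
  )
}

# Well-separated Gaussian blobs in the six-predictor space: fast,
# controlled features for classifier tests without the simulator.
blob_features <- function(n_per_class = 12, seed = 1, sep = 6,
                          animals = "A1", jitter_sd = 0.2,
                          shift = setNames(numeric(0), character(0))) {
  set.seed(seed)
  centres <- list(
    D = c(0, 0, 0, 0, 0, 0), F = c(sep, 0, 0, 0, 0, 0),
    G = c(0, sep, 0, 0, 0, 0), R = c(0, 0, sep, 0, 0, 0),
    T = c(0, 0, 0, sep, 0, 0), W = c(0, 0, 0, 0, sep, 0)
  )
  rows <- list()
  k <- 0
  for (a in animals) {
    off <- if (a %in% names(shift)) shift[[a]] else 0
    for (b in names(centres)) {
      m <- matrix(rnorm(n_per_class * 6, sd = jitter_sd), ncol = 6)
      m <- sweep(m, 2, centres[[b]] + off, `+`)
      for (i in seq_len(n_per_class)) {
        k <- k + 1
        rows[[k]] <- tibble::tibble(
          animal_id = a,
          start_time = utc("2017-10-06 04:00:00") + k * 30,
          n = 40L, mnz = m[i, 1], sdz = abs(m[i, 2]) + 1, wmz = m[i, 3],
          icvz = m[i, 4], kz = m[i, 5], sz = m[i, 6],
          degenerate = FALSE, label = b
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# A minimal prediction-set-shaped tibble for fusion tests (only the
# columns the fusion operations read).
fake_preds <- function(times, svm = "R", mean_ = "R", majority = "R",
                       animal = "M1") {
  n <- length(times)
  tibble::tibble(
    animal_id = rep(animal, n),
    start_time = times,
    svm_label = rep_len(svm, n),
    mean_label = rep_len(mean_, n),
    majority_label = rep_len(majority, n)
  )
}

# Small labelled feature set from the real simulator (for cross-validation
# tests exercising the genuine signal models).
sim_features <- function(seed = 11, n_animals = 2, bursts_per_class = 12,
                         shifted_animal = NULL) {
  sc <- make_captive_scenario(seed = seed, n_animals = n_animals,
                              bursts_per_class = bursts_per_class,
                              shifted_animal = shifted_animal)
  feature_table(generate_bursts(sc)$bursts)
}
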