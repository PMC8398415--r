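#' Periodogram of a burst at the Fourier frequencies
#'
#' Standard periodogram of the mean-removed series, evaluated at the
#' Fourier frequencies w_j = 2*pi*j/n for j = 1, ..., q with q = n/2 for
#' even n and q = (n - 1)/2 for odd n. The series mean is removed first so
#' the DC term never enters the spectral summary. Ordinates are
#' |DFT_j|^2 / n (any positive scaling cancels in the weighted mean).
#'
#' @param samples Numeric vector, length >= 4.
#' @return A list with `frequencies` (radians/sample, in (0, pi]),
#'   `ordinates` (non-negative), and `n`.
#' @export
periodogram <- function(samples) {
  n <- length(samples)
  if (n < 4) stop("periodogram requires at least 4 samples, got ", n)
  q <- if (n %% 2 == 0) n %/% 2 else (n - 1L) %/% 2
  j <- seq_len(q)
  d <- fft(samples - mean(samples))
  list(
    frequencies = 2 * pi * j / n,
    ordinates = Mod(d[j + 1L])^2 / n,
    n = n
  )
}

# Sentinel for the inverse coefficient of variation of a constant burst;
# kept finite so classifiers can consume it, with a degeneracy flag beside.
ICV_SENTINEL <- 1e12

#' Compute the six burst predictors
#'
#' From a burst's z-axis samples: mean (`mnz`), standard deviation (`sdz`,
#' population form, divisor n, by default), periodogram-weighted mean
#' Fourier frequency (`wmz`, radians/sample), inverse coefficient of
#' variation (`icvz` = mnz/sdz), kurtosis (`kz`, Pearson, not excess) and
#' skewness (`sz`, standardised third moment). `wmz` is the ordinate-
#' weighted mean of the Fourier frequencies, sum(w * I(w)) / sum(I(w)),
#' on the mean-removed series.
#'
#' Degenerate (zero-variance) bursts yield `sdz = 0`, `sz = kz = 0`,
#' `wmz = 0` (all ordinates zero) and `icvz` set to the large sentinel
#' `1e12` (signed by the mean) with `degenerate = TRUE`.
#'
#' @param samples Numeric vector of z-axis samples (length >= 4).
#' @param sd_divisor `"n"` (population, default) or `"n-1"` (sample).
#' @param wmz_mode `"weighted_frequency"` (default) or `"mean_ordinate"`
#'   (the alternative reading: the average periodogram ordinate).
#' @return A named list with `mnz`, `sdz`, `wmz`, `icvz`, `kz`, `sz`, `n`,
#'   `degenerate`.
#' @examples
#' t <- 0:39
#' f <- compute_features(cos(2 * pi * 5 * t / 40))
#' f$wmz  # 2*pi*5/40
#' @export
compute_features <- function(samples, sd_divisor = c("n", "n-1"),
                             wmz_mode = c("weighted_frequency",
                                          "mean_ordinate")) {
  sd_divisor <- match.arg(sd_divisor)
  wmz_mode <- match.arg(wmz_mode)
  n <- length(samples)
  if (n < 4) stop("compute_features requires at least 4 samples, got ", n)

  mnz <- mean(samples)
  centred <- samples - mnz
  m2 <- mean(centred^2)
  sdz <- if (sd_divisor == "n") sqrt(m2) else sqrt(m2 * n / (n - 1))

  pg <- periodogram(samples)
  tot <- sum(pg$ordinates)
  wmz <- if (wmz_mode == "mean_ordinate") {
    mean(pg$ordinates)
  } else if (tot > 0) {
    sum(pg$frequencies * pg$ordinates) / tot
  } else 0

  degenerate <- m2 == 0
  if (degenerate) {
    list(mnz = mnz, sdz = sdz, wmz = 0,
         icvz = ICV_SENTINEL * if (mnz < 0) -1 else 1,
         kz = 0, sz = 0, n = n, degenerate = TRUE)
  } else {
    list(
      mnz = mnz, sdz = sdz, wmz = wmz,
      icvz = mnz / sdz,
      kz = mean(centred^4) / m2^2,
      sz = mean(centred^3) / m2^1.5,
      n = n, degenerate = FALSE
    )
  }
}

FEATURE_COLS <- c("mnz", "sdz", "wmz", "icvz", "kz", "sz")

#' Feature table for a burst collection
#'
#' Applies [compute_features()] to every burst, carrying the burst key and
#' label through. Per-burst failures (e.g. too-short bursts) are collected
#' into an `errors` attribute rather than aborting the table.
#'
#' @param bursts Burst tibble (see [acc_bursts()]).
#' @param ... Passed to [compute_features()].
#' @return A tibble with columns `animal_id`, `start_time`, `n`, `mnz`,
#'   `sdz`, `wmz`, `icvz`, `kz`, `sz`, `degenerate`, `label`, one row per
#'   successful burst, input order preserved; failed rows are reported in
#'   `attr(, "errors")`.
#' @export
feature_table <- function(bursts, ...) {
  rows <- vector("list", nrow(bursts))
  errs <- list()
  for (i in seq_len(nrow(bursts))) {
    fv <- tryCatch(compute_features(bursts$samples[[i]], ...),
                   error = function(e) e)
    if (inherits(fv, "error")) {
      errs[[length(errs) + 1L]] <- tibble(
        animal_id = bursts$animal_id[i],
        start_time = bursts$start_time[i],
        message = conditionMessage(fv)
      )
    } else {
      rows[[i]] <- tibble(
        animal_id = bursts$animal_id[i],
        start_time = bursts$start_time[i],
        n = fv$n, mnz = fv$mnz, sdz = fv$sdz, wmz = fv$wmz,
        icvz = fv$icvz, kz = fv$kz, sz = fv$sz,
        degenerate = fv$degenerate,
        label = bursts$label[i]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      animal_id = character(), start_time = as.POSIXct(character(), tz = "UTC"),
      n = integer(), mnz = double(), sdz = double(), wmz = double(),
      icvz = double(), kz = double(), sz = double(),
      degenerate = logical(), label = character()
    )
  }
  attr(out, "errors") <- dplyr::bind_rows(errs)
  out
}

#' Write / read a feature table CSV
#'
#' Dialect: `animal_id,timestamp,n,mnz,sdz,wmz,icvz,kz,sz,label`, ISO-8601
#' UTC timestamps, empty label for UNKNOWN.
#'
#' @param features Feature tibble from [feature_table()].
#' @param path File path.
#' @return `path` invisibly (write); the feature tibble (read).
#' @export
write_features <- function(features, path) {
  df <- data.frame(
    animal_id = features$animal_id,
    timestamp = format_utc(features$start_time),
    n = features$n,
    mnz = features$mnz, sdz = features$sdz, wmz = features$wmz,
    icvz = features$icvz, kz = features$kz, sz = features$sz,
    label = ifelse(features$label == "UNKNOWN", "", features$label),
    stringsAsFactors = FALSE
  )
  fwrite(df, path, sep = ",", eol = "\n", quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  raw <- fread(path, sep = ",", header = TRUE, data.table = FALSE,
               colClasses = list(character = c("animal_id", "timestamp", "label")),
               na.strings = NULL)
  tibble(
    animal_id = raw$animal_id,
    start_time = parse_utc(raw$timestamp),
    n = as.integer(raw$n),
    mnz = raw$mnz, sdz = raw$sdz, wmz = raw$wmz,
    icvz = raw$icvz, kz = raw$kz, sz = raw$sz,
    degenerate = raw$sdz == 0,
    label = ifelse(nzchar(raw$label), raw$label, "UNKNOWN")
  )
}
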