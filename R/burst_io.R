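#' Build a burst table in memory
#'
#' The in-memory representation of a burst stream is a tibble with one row
#' per burst: `animal_id`, `start_time` (POSIXct, UTC, second resolution),
#' `sampling_rate` (Hz), `label` (one of D, F, G, R, T, W, MIXED, UNKNOWN),
#' `firmware`, and `samples` (list column of numeric z-axis vectors).
#'
#' @param animal_id Character vector of animal identifiers.
#' @param start_time POSIXct (UTC) burst start times.
#' @param sampling_rate Sampling rate(s) in Hz.
#' @param samples List of numeric sample vectors (heave/z axis).
#' @param label Behaviour labels; defaults to `"UNKNOWN"`.
#' @param firmware Firmware tag(s).
#' @return A tibble sorted by (`animal_id`, `start_time`).
#' @export
acc_bursts <- function(animal_id, start_time, sampling_rate, samples,
                       label = "UNKNOWN", firmware = "A") {
  stopifnot(inherits(start_time, "POSIXct"), is.list(samples))
  bad <- setdiff(unique(label), BURST_LABELS)
  if (length(bad) > 0) {
    stop("invalid burst label(s): ", paste(bad, collapse = ", "))
  }
  out <- tibble(
    animal_id = as.character(animal_id),
    start_time = as.POSIXct(start_time, tz = "UTC"),
    sampling_rate = sampling_rate,
    label = as.character(label),
    firmware = as.character(firmware),
    samples = samples
  )
  out[order(out$animal_id, out$start_time), ]
}

parse_utc <- function(x) {
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$", x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  out[ok] <- as.POSIXct(x[ok], tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  out
}

format_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Read accelerometer bursts from CSV
#'
#' Expects the header `animal_id,timestamp,sampling_rate_hz,label,z0,...`,
#' ISO-8601 UTC timestamps (`YYYY-MM-DDThh:mm:ssZ`), "." decimals and LF
#' endings. An empty label means UNKNOWN. Rows are validated against the
#' collar configuration: the number of z samples must equal
#' `config$samples_per_burst` and the declared rate must match
#' `config$sampling_rate`. Invalid rows are rejected, never silently
#' dropped: each appears in the `rejected` report with its row number and
#' a reason. Duplicate (`animal_id`, `timestamp`) pairs reject all rows
#' involved, naming the rows.
#'
#' @param path CSV file path.
#' @param config A [collar_config()] describing the expected regime.
#' @return A list with `bursts` (tibble as [acc_bursts()], sorted by
#'   animal and time) and `rejected` (tibble `row`, `animal_id`,
#'   `timestamp`, `reason`).
#' @export
read_bursts <- function(path, config) {
  stopifnot(inherits(config, "collar_config"), file.exists(path))
  raw <- fread(path, sep = ",", header = TRUE, colClasses = "character",
               na.strings = NULL, fill = TRUE, data.table = FALSE)
  zcols <- grep("^z\\d+$", names(raw), value = TRUE)
  zcols <- zcols[order(as.integer(sub("^z", "", zcols)))]
  n <- nrow(raw)
  reject <- character(n)

  ts <- parse_utc(raw$timestamp)
  reject[is.na(ts) & !nzchar(reject)] <- "malformed timestamp"

  rate <- suppressWarnings(as.numeric(raw$sampling_rate_hz))
  rate_ok <- !is.na(rate) &
    abs(normalise_rate_vec(rate) - config$sampling_rate) < 1e-6
  reject[!rate_ok & !nzchar(reject)] <- "sampling-rate mismatch"

  if (length(zcols) < config$samples_per_burst) {
    stop(sprintf("file has %d sample columns but config expects %d",
                 length(zcols), config$samples_per_burst))
  }
  zmat <- matrix(suppressWarnings(as.numeric(as.matrix(raw[zcols]))),
                 nrow = n)
  n_samples <- rowSums(!is.na(zmat) & nzchar(as.matrix(raw[zcols])))
  count_bad <- n_samples != config$samples_per_burst |
    apply(zmat[, seq_len(config$samples_per_burst), drop = FALSE], 1L,
          function(r) anyNA(r))
  reject[count_bad & !nzchar(reject)] <- "sample-count mismatch"

  label <- ifelse(nzchar(raw$label), raw$label, "UNKNOWN")
  reject[!(label %in% BURST_LABELS) & !nzchar(reject)] <- "invalid label"

  key <- paste(raw$animal_id, raw$timestamp)
  dup <- key %in% key[duplicated(key)] & !nzchar(reject)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      rows <- which(key == k & dup)
      reject[rows] <- sprintf("duplicate (animal_id, timestamp): rows %s",
                              paste(rows, collapse = ", "))
    }
  }

  keep <- !nzchar(reject)
  rejected <- tibble(
    row = which(!keep),
    animal_id = raw$animal_id[!keep],
    timestamp = raw$timestamp[!keep],
    reason = reject[!keep]
  )
  bursts <- acc_bursts(
    animal_id = raw$animal_id[keep],
    start_time = ts[keep],
    sampling_rate = config$sampling_rate,
    samples = lapply(which(keep), function(i)
      unname(zmat[i, seq_len(config$samples_per_burst)])),
    label = label[keep],
    firmware = config$firmware
  )
  list(bursts = bursts, rejected = rejected)
}

normalise_rate_vec <- function(r) ifelse(abs(r - 33.3) < 0.05, 100 / 3, r)

#' Write accelerometer bursts to CSV
#'
#' Inverse of [read_bursts()]: one row per burst in the canonical dialect.
#' All bursts must share one sample count. UNKNOWN labels are written as
#' the empty string; 100/3 Hz is written as 33.3.
#'
#' @param bursts Burst tibble as produced by [acc_bursts()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bursts <- function(bursts, path) {
  lens <- lengths(bursts$samples)
  if (length(unique(lens)) > 1) {
    stop("bursts with mixed sample counts cannot share one file")
  }
  nz <- if (nrow(bursts) > 0) lens[1] else 0L
  zmat <- do.call(rbind, bursts$samples)
  df <- data.frame(
    animal_id = bursts$animal_id,
    timestamp = format_utc(bursts$start_time),
    sampling_rate_hz = format_rate(bursts$sampling_rate),
    label = ifelse(bursts$label == "UNKNOWN", "", bursts$label),
    stringsAsFactors = FALSE
  )
  if (nz > 0) {
    zdf <- as.data.frame(zmat)
    names(zdf) <- paste0("z", seq_len(nz) - 1L)
    df <- cbind(df, zdf)
  }
  fwrite(df, path, sep = ",", eol = "\n", quote = FALSE)
  invisible(path)
}

format_rate <- function(r) {
  ifelse(abs(r - 100 / 3) < 1e-9, "33.3", format(r, trim = TRUE))
}

#' Keep only single-behaviour bursts
#'
#' Ground-truthed streams contain bursts during which the behaviour
#' changed; these carry the label MIXED and are discarded before model
#' training, explicitly and countably.
#'
#' @param bursts Burst tibble with populated labels.
#' @return A list with `kept` (bursts labelled with one of the six
#'   behaviours) and `discarded_count` (everything else: MIXED or
#'   UNKNOWN).
#' @export
filter_single_behaviour <- function(bursts) {
  keep <- bursts$label %in% BEHAVIOURS
  list(kept = bursts[keep, ], discarded_count = sum(!keep))
}

#' Read GPS fixes from CSV
#'
#' Expects the header `animal_id,timestamp,lat,lon` with ISO-8601 UTC
#' timestamps and WGS84 decimal degrees. Out-of-range coordinates,
#' malformed timestamps and duplicate (`animal_id`, `timestamp`) rows are
#' rejected with a per-row report.
#'
#' @param path CSV file path.
#' @return A list with `fixes` (tibble `animal_id`, `time`, `lat`, `lon`
#'   sorted by animal and time, stable for ties) and `rejected`.
#' @export
read_gps <- function(path) {
  stopifnot(file.exists(path))
  raw <- fread(path, sep = ",", header = TRUE, colClasses = "character",
               na.strings = NULL, data.table = FALSE)
  n <- nrow(raw)
  reject <- character(n)

  ts <- parse_utc(raw$timestamp)
  reject[is.na(ts) & !nzchar(reject)] <- "malformed timestamp"

  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))
  bad_coord <- is.na(lat) | is.na(lon) | abs(lat) > 90 | abs(lon) > 180
  reject[bad_coord & !nzchar(reject)] <- "coordinate out of range"

  key <- paste(raw$animal_id, raw$timestamp)
  dup <- key %in% key[duplicated(key)] & !nzchar(reject)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      rows <- which(key == k & dup)
      reject[rows] <- sprintf("duplicate (animal_id, timestamp): rows %s",
                              paste(rows, collapse = ", "))
    }
  }

  keep <- !nzchar(reject)
  fixes <- tibble(
    animal_id = raw$animal_id[keep],
    time = ts[keep],
    lat = lat[keep],
    lon = lon[keep]
  )
  fixes <- fixes[order(fixes$animal_id, fixes$time), ]
  rejected <- tibble(
    row = which(!keep),
    animal_id = raw$animal_id[!keep],
    timestamp = raw$timestamp[!keep],
    reason = reject[!keep]
  )
  list(fixes = fixes, rejected = rejected)
}

#' Write GPS fixes to CSV
#'
#' @param fixes Tibble `animal_id`, `time`, `lat`, `lon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gps <- function(fixes, path) {
  df <- data.frame(
    animal_id = fixes$animal_id,
    timestamp = format_utc(fixes$time),
    lat = fixes$lat,
    lon = fixes$lon,
    stringsAsFactors = FALSE
  )
  fwrite(df, path, sep = ",", eol = "\n", quote = FALSE)
  invisible(path)
}
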