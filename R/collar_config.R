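#' Collar recording configuration
#'
#' Describes one accelerometer duty cycle: sampling rate, burst length,
#' burst spacing, and the resulting fixed number of samples per burst.
#' The nominal 33.3 Hz collar rate is treated exactly as 100/3 Hz so that
#' resampling ratios stay rational (3.3 s x 100/3 Hz = 110 samples).
#'
#' @param sampling_rate Sampling rate in Hz (> 0). The value 33.3 is
#'   normalised to 100/3.
#' @param burst_length Burst duration in seconds (> 0).
#' @param burst_interval Spacing between burst starts in seconds (> 0).
#' @param firmware Free-text firmware tag carried onto ingested bursts.
#'
#' @return An object of class `collar_config` with fields `sampling_rate`,
#'   `burst_length`, `burst_interval`, `samples_per_burst`, `firmware`.
#' @examples
#' collar_config(10, 3.6, 120)$samples_per_burst  # 36
#' @export
collar_config <- function(sampling_rate, burst_length, burst_interval = 30,
                          firmware = "A") {
  sampling_rate <- normalise_rate(sampling_rate)
  stopifnot(sampling_rate > 0, burst_length > 0, burst_interval > 0)
  structure(
    list(
      sampling_rate = sampling_rate,
      burst_length = burst_length,
      burst_interval = burst_interval,
      samples_per_burst = as.integer(round(sampling_rate * burst_length)),
      firmware = firmware
    ),
    class = "collar_config"
  )
}

# 33.3 Hz is the collar's display value for 100/3 Hz.
normalise_rate <- function(rate) {
  if (abs(rate - 33.3) < 0.05) 100 / 3 else rate
}

#' Preset collar configurations
#'
#' The four recording regimes used across captive and free-ranging
#' deployments: firmware A at 10 Hz x 4.0 s or 33.3 Hz x 3.3 s bursts every
#' 30 s (captive), firmware B at 10.54 Hz x 3.8 s every 30 s (captive
#' female), and firmware B at 10 Hz x 3.6 s bursts every 120 s
#' (free-ranging).
#'
#' @param name One of `"captive_10hz"`, `"captive_33hz"`,
#'   `"captive_female"`, `"free_ranging"`.
#' @return A [collar_config()].
#' @export
collar_preset <- function(name = c("captive_10hz", "captive_33hz",
                                   "captive_female", "free_ranging")) {
  name <- match.arg(name)
  switch(name,
    captive_10hz   = collar_config(10, 4.0, 30, firmware = "A"),
    captive_33hz   = collar_config(33.3, 3.3, 30, firmware = "A"),
    captive_female = collar_config(10.54, 3.8, 30, firmware = "B"),
    free_ranging   = collar_config(10, 3.6, 120, firmware = "B")
  )
}

#' @export
print.collar_config <- function(x, ...) {
  cat(sprintf(
    "<collar_config> %.4g Hz, %.3g s bursts every %.4g s (%d samples, firmware %s)\n",
    x$sampling_rate, x$burst_length, x$burst_interval,
    x$samples_per_burst, x$firmware
  ))
  invisible(x)
}
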