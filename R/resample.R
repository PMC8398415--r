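#' Rational (polyphase) resampling of a burst
#'
#' Changes the sampling rate of a burst by a rational factor `up/down`,
#' applying a linear-phase FIR anti-aliasing low-pass before decimation.
#' The filter is a Kaiser-window (beta = 5) windowed-sinc design with
#' cutoff at the narrower of the two Nyquist frequencies and half-length
#' 10 x max(up, down) taps, the standard polyphase default. Each polyphase
#' branch is normalised to unit gain so a constant (DC) signal is
#' preserved exactly, and the input is edge-replicated so the burst ends
#' carry no startup transient. The output length is
#' `ceiling(n * up / down)`; start time and label are preserved.
#'
#' The nominal collar rate 33.3 Hz is interpreted as exactly 100/3 Hz, so
#' 33.3 -> 10 Hz resampling uses up = 3, down = 10 (110 samples -> 33).
#'
#' @param burst A one-row burst tibble (see [acc_bursts()]) or a list with
#'   fields `samples` and `sampling_rate`.
#' @param target_rate Desired sampling rate in Hz.
#' @return The burst with `samples` resampled and `sampling_rate` set to
#'   `target_rate` (33.3 normalised to 100/3).
#' @export
resample_burst <- function(burst, target_rate) {
  target_rate <- normalise_rate(target_rate)
  if (is.data.frame(burst)) {
    stopifnot(nrow(burst) == 1)
    src_rate <- normalise_rate(burst$sampling_rate[[1]])
    x <- burst$samples[[1]]
  } else {
    src_rate <- normalise_rate(burst$sampling_rate)
    x <- burst$samples
  }
  ratio <- rational_ratio(target_rate / src_rate)
  y <- resample_poly(x, ratio$up, ratio$down)
  if (is.data.frame(burst)) {
    burst$samples[[1]] <- y
    burst$sampling_rate[[1]] <- target_rate
  } else {
    burst$samples <- y
    burst$sampling_rate <- target_rate
  }
  burst
}

# Continued-fraction rational approximation with small denominator.
# Errors out when the rate ratio is not (close to) a small rational,
# which the collar regimes always are.
rational_ratio <- function(r, max_den = 1000, tol = 1e-9) {
  stopifnot(r > 0, is.finite(r))
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  x <- r
  for (i in 1:64) {
    a <- floor(x)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(r - p1 / q1) < tol * r) break
    frac <- x - a
    if (frac < 1e-15) break
    x <- 1 / frac
  }
  if (abs(r - p1 / q1) >= tol * r) {
    stop(sprintf("unsupported resampling ratio %.10g: no rational p/q with q <= %d",
                 r, max_den))
  }
  g <- gcd(p1, q1)
  list(up = as.integer(p1 / g), down = as.integer(q1 / g))
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

# Polyphase resampling core: zero-stuff by `up`, FIR low-pass, take every
# `down`-th sample. Output length ceiling(n * up / down).
resample_poly <- function(x, up, down) {
  stopifnot(up >= 1, down >= 1)
  n <- length(x)
  if (up == down) return(x)
  h <- resample_filter(up, down)
  half <- (length(h) - 1L) / 2L

  # replicate edges so the filter never sees an artificial step to zero
  npad <- ceiling(half / up) + 1L
  xp <- c(rep(x[1], npad), x, rep(x[n], npad))

  xup <- numeric(length(xp) * up)
  xup[seq(1L, by = up, length.out = length(xp))] <- xp

  y <- stats::convolve(xup, rev(h), type = "open")
  # y[k] = sum_j h[j] * xup[k - j + 1]; the filter centre sits at half + 1,
  # and original sample i lives at upsampled index (npad + i - 1) * up + 1.
  n_out <- ceiling(n * up / down)
  idx <- npad * up + half + 1L + (seq_len(n_out) - 1L) * down
  y[idx]
}

# Kaiser-window (beta = 5) windowed-sinc low-pass, cutoff at the new
# Nyquist, gain `up`, with each polyphase branch normalised to unit DC
# gain so constants pass through exactly.
resample_filter <- function(up, down) {
  m <- max(up, down)
  half <- 10L * m
  n_taps <- 2L * half + 1L
  k <- seq(-half, half)
  fc <- 1 / (2 * m)  # cycles per sample at the upsampled rate
  hsinc <- 2 * fc * sinc(2 * fc * k)
  h <- up * hsinc * signal::kaiser(n_taps, beta = 5)
  for (phase in seq_len(up) - 1L) {
    sel <- which((k %% up) == phase)
    s <- sum(h[sel])
    if (s != 0) h[sel] <- h[sel] / s
  }
  h
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))
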