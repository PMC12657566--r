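# Internal helpers: condition constructors, FIR filtering, band-limited noise.

stop_param <- function(msg) abort(msg, class = "nirsconnect_parameter_error")
stop_data  <- function(msg) abort(msg, class = "nirsconnect_data_error")
stop_config <- function(msg) abort(msg, class = "nirsconnect_config_error")
stop_state <- function(msg) abort(msg, class = "nirsconnect_state_error")
stop_format <- function(msg) abort(msg, class = "nirsconnect_format_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Design a Hamming-windowed sinc low-pass kernel
#'
#' Kernel length is set by the requested transition width using the standard
#' Hamming approximation (width ~ 3.3 / N normalized); the cutoff is the -6 dB
#' point.
#'
#' @param fc cutoff frequency, Hz (-6 dB point)
#' @param fs sampling rate, Hz
#' @param transition transition width, Hz
#' @param max_length optional cap on kernel length (odd), e.g. the signal length
#' @return numeric kernel, odd length, unit DC gain
#' @keywords internal
fir_lowpass_kernel <- function(fc, fs, transition, max_length = Inf) {
  n <- ceiling(3.3 * fs / transition)
  if (n %% 2 == 0) n <- n + 1
  if (n > max_length) {
    n <- as.integer(max_length)
    if (n %% 2 == 0) n <- n - 1L
  }
  if (n < 3) n <- 3L
  m <- (n - 1) / 2
  t <- seq(-m, m)
  h <- (2 * fc / fs) * sinc(2 * fc * t / fs)
  w <- 0.54 + 0.46 * cos(pi * t / m)  # Hamming
  h <- h * w
  h / sum(h)
}

# Band-pass kernel with independent transition widths per edge: the low edge
# is realized as (delta - lowpass) and convolved with the high-edge lowpass.
# -6 dB points sit at band[1] and band[2]; stopbands begin one transition
# width beyond each edge.
fir_bandpass_kernel <- function(fs, band, transitions, max_length = Inf) {
  if (band[2] >= fs / 2) stop_config("upper cutoff at or above Nyquist frequency")
  if (band[1] >= band[2]) stop_config("band edges must be ordered")
  fc_lo <- max(band[1] - transitions[1] / 2, band[1] / 2)
  fc_hi <- band[2] + transitions[2] / 2
  lp_hi <- fir_lowpass_kernel(fc_hi, fs, transitions[2], max_length)
  lp_lo <- fir_lowpass_kernel(fc_lo, fs, transitions[1], max_length)
  hp <- -lp_lo
  hp[(length(hp) + 1) / 2] <- hp[(length(hp) + 1) / 2] + 1
  h <- stats::convolve(hp, rev(lp_hi), type = "open")
  h
}

# Zero-phase filtering by convolution with a symmetric odd-length kernel,
# mirror-padded at the edges. Output length equals input length.
apply_fir <- function(x, h) {
  n <- length(x)
  m <- (length(h) - 1) / 2
  # reflected index map (triangular wave of period 2n) handles m >= n too
  idx <- seq(-m + 1, n + m)
  p <- (idx - 1) %% (2 * n)
  p <- ifelse(p >= n, 2 * n - 1 - p, p) + 1
  xp <- x[p]
  y <- stats::convolve(xp, rev(h), type = "filter")  # valid part
  stopifnot(length(y) == n)
  y
}

# Zero-phase band-pass of a vector; kernel capped at the signal length.
fir_bandpass <- function(x, fs, band, transitions = c(0.2, 0.2)) {
  h <- fir_bandpass_kernel(fs, band, transitions, max_length = length(x))
  apply_fir(x, h)
}

# Gaussian noise band-limited to [f1, f2] Hz by FFT masking, scaled to unit SD.
band_limited_noise <- function(n, fs, band) {
  x <- rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  keep <- f >= band[1] & f <= band[2]
  xf <- fft(x)
  xf[!keep] <- 0
  y <- Re(fft(xf, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) return(y)
  y / s
}

# Derive a reproducible child seed (< 2^31) from a base seed and a tag.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * k) %% 2147483647
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x == floor(x) && x >= 0

check_stage <- function(rec, expected, op) {
  if (!identical(rec$stage, expected)) {
    stop_state(sprintf(
      "%s() expects a recording at stage '%s' but got '%s'; the preprocessing chain order is fixed",
      op, expected, rec$stage %||% "<none>"
    ))
  }
  invisible(TRUE)
}
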