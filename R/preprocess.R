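# Zero-phase FIR preprocessing.
#
# Both modalities share one very-low-frequency low-pass (cutoff 0.625 Hz):
# acceleration is smoothed so that only the gravity-direction trajectory of
# the arm survives, and the rectified sEMG is smoothed into its mean-absolute-
# value (MAV) envelope. Tap counts scale with the sample rate (8192 taps at
# 125 Hz, 65536 at 2 kHz) so both filters span the same ~65 s of signal; the
# group delay of (n_taps - 1)/2 samples is compensated after filtering so the
# output is aligned with the input (zero-phase).

#' FIR low-pass filter specification
#'
#' @param n_taps Number of filter coefficients (>= 3).
#' @param cutoff_hz Ideal-sinc cutoff frequency in Hz.
#' @param rate_hz Sampling rate in Hz; must exceed `2 * cutoff_hz`.
#' @return An object of class `fir_spec`.
#' @export
fir_spec <- function(n_taps, cutoff_hz, rate_hz) {
  assert_that(is_scalar_number(n_taps) && n_taps >= 3 && n_taps == round(n_taps),
              "n_taps must be an integer >= 3")
  assert_that(is_scalar_number(cutoff_hz) && cutoff_hz > 0,
              "cutoff_hz must be > 0")
  assert_that(is_scalar_number(rate_hz) && rate_hz > 2 * cutoff_hz,
              "cutoff_hz must be below the Nyquist frequency rate_hz/2")
  structure(list(n_taps = as.integer(n_taps), cutoff_hz = cutoff_hz,
                 rate_hz = rate_hz), class = "fir_spec")
}

#' Default filter specifications for the two modalities
#'
#' @return A list with elements `accel` (8192 taps, 0.625 Hz at 125 Hz) and
#'   `emg` (65536 taps, 0.625 Hz at 2 kHz).
#' @export
default_filters <- function() {
  list(accel = fir_spec(8192, 0.625, 125),
       emg = fir_spec(65536, 0.625, 2000))
}

# Symmetric (non-periodic) minimum 4-term Blackman-Harris window.
blackman_harris <- function(n) {
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  k <- seq_len(n) - 1
  a[1] - a[2] * cos(2 * pi * k / (n - 1)) +
    a[3] * cos(4 * pi * k / (n - 1)) - a[4] * cos(6 * pi * k / (n - 1))
}

#' Design the windowed-sinc low-pass filter of a [fir_spec()]
#'
#' Ideal-sinc impulse response truncated to `n_taps` samples, tapered by the
#' minimum 4-term Blackman-Harris window, and normalized to exactly unit DC
#' gain. The coefficient set is symmetric (linear phase).
#'
#' @param spec A [fir_spec()].
#' @return Numeric vector of `n_taps` coefficients summing to 1.
#' @export
design_lowpass <- function(spec) {
  assert_that(inherits(spec, "fir_spec"), "spec must be a fir_spec")
  fc <- spec$cutoff_hz / spec$rate_hz            # cycles per sample
  x <- seq_len(spec$n_taps) - 1 - (spec$n_taps - 1) / 2
  h <- 2 * fc * sinc(2 * fc * x)
  h <- h * blackman_harris(spec$n_taps)
  h / sum(h)
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

# Reflect x about its ends to pad n samples on each side; folds repeatedly so
# n may exceed length(x).
reflect_indices <- function(len, n) {
  idx <- seq.int(1 - n, len + n)
  period <- 2 * len - 2
  if (len == 1) return(rep(1L, length(idx)))
  m <- (idx - 1) %% period
  as.integer(ifelse(m < len, m + 1, period - m + 1))
}

#' Apply a zero-phase FIR low-pass filter
#'
#' Filters each column of `x` with the coefficients of `spec` by FFT
#' convolution, compensating the linear-phase group delay of
#' `(n_taps - 1)/2` samples exactly (including the half-sample delay of
#' even-length designs) by a frequency-domain phase advance, and handling the
#' edges by symmetric reflection padding. Output has the same length as the
#' input and zero phase lag in the passband.
#'
#' @param x Numeric vector or matrix (columns filtered independently).
#' @param spec A [fir_spec()], or a raw coefficient vector.
#' @return Filtered signal, same shape as `x`.
#' @export
zero_phase_filter <- function(x, spec) {
  h <- if (is.numeric(spec) && !inherits(spec, "fir_spec")) spec else design_lowpass(spec)
  mat <- is.matrix(x)
  xm <- if (mat) x else matrix(x, ncol = 1)
  assert_that(nrow(xm) > 0, "input signal must be non-empty")
  assert_that(all(is.finite(xm)), "input signal must be finite")
  len <- nrow(xm)
  n_taps <- length(h)
  pad <- ceiling((n_taps - 1) / 2)
  ridx <- reflect_indices(len, pad)
  n <- nextn(len + 2 * pad + 1)
  # advance by the group delay: multiply the transfer function by
  # exp(+j*omega*tau), tau = (n_taps - 1)/2 samples (possibly half-integer)
  tau <- (n_taps - 1) / 2
  kk <- c(seq.int(0, floor(n / 2)), seq.int(-(ceiling(n / 2) - 1), -1))
  H <- fft(c(h, numeric(n - n_taps))) * exp(2i * pi * kk * tau / n)
  out <- matrix(0, len, ncol(xm))
  for (j in seq_len(ncol(xm))) {
    xp <- xm[ridx, j]
    y <- Re(fft(fft(c(xp, numeric(n - length(xp)))) * H, inverse = TRUE)) / n
    out[, j] <- y[pad + seq_len(len)]
  }
  if (mat) out else out[, 1]
}

#' Rectified, low-pass filtered sEMG envelope (mean absolute value)
#'
#' Rectifies the sEMG and applies the zero-phase low-pass of `spec`; residual
#' negative filter ripple is clamped to zero so the envelope is nonnegative.
#'
#' @param emg Numeric vector of raw sEMG samples.
#' @param spec A [fir_spec()]; defaults to the 65536-tap, 0.625 Hz design.
#' @return Nonnegative envelope, same length as `emg`.
#' @export
emg_envelope <- function(emg, spec = default_filters()$emg) {
  pmax(zero_phase_filter(abs(emg), spec), 0)
}

#' Normalize an envelope by its time average
#'
#' Divides the envelope by its full-recording mean so the result has mean
#' exactly 1; makes amplitudes comparable across channels, subjects and
#' amplifier gains.
#'
#' @param env Nonnegative numeric vector.
#' @return Envelope with mean 1.
#' @export
normalize_envelope <- function(env) {
  m <- mean(env)
  assert_that(is.finite(m) && m > 1e-12,
              "silent channel: envelope mean is zero or near zero")
  env / m
}

#' Preprocess all channels of a recording
#'
#' Low-pass filters each node's acceleration and replaces each node's raw
#' sEMG with its normalized MAV envelope. Filtering runs over the whole
#' recording before any windowing so segments shorter than the filter length
#' are still handled consistently.
#'
#' @param rec A [recording()].
#' @param filters List with `accel` and `emg` [fir_spec()]s; see
#'   [default_filters()].
#' @param normalize Normalize the sEMG envelope by its recording-wide mean
#'   (default `TRUE`).
#' @return A `recording` whose streams are the filtered acceleration and the
#'   normalized envelope, with attribute `preprocessed = TRUE`.
#' @export
preprocess_recording <- function(rec, filters = default_filters(),
                                 normalize = TRUE) {
  validate_recording(rec)
  h_acc <- design_lowpass(filters$accel)
  h_emg <- design_lowpass(filters$emg)
  nodes <- lapply(rec$nodes, function(n) {
    assert_that(abs(n$accel_rate_hz - filters$accel$rate_hz) < 1e-9 &&
                  abs(n$emg_rate_hz - filters$emg$rate_hz) < 1e-9,
                "filter specs must match the stream sample rates")
    acc_f <- zero_phase_filter(n$accel, h_acc)
    env <- pmax(zero_phase_filter(abs(n$emg), h_emg), 0)
    if (normalize) env <- normalize_envelope(env)
    node_stream(n$node_name, acc_f, env, n$accel_rate_hz, n$emg_rate_hz)
  })
  out <- recording(rec$subject_id, nodes, rec$segments, rec$meta)
  attr(out, "preprocessed") <- TRUE
  out
}

#' Frequency response magnitude of a filter design
#'
#' @param h Coefficient vector (e.g. from [design_lowpass()]).
#' @param freq_hz Frequencies at which to evaluate, in Hz.
#' @param rate_hz Sampling rate the design assumes.
#' @return Magnitude of the transfer function at `freq_hz`.
#' @export
filter_response <- function(h, freq_hz, rate_hz) {
  k <- seq_along(h) - 1
  vapply(freq_hz, function(f) {
    Mod(sum(h * exp(-2i * pi * f / rate_hz * k)))
  }, numeric(1))
}
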