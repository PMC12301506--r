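#' Trapezoidal integral
#'
#' Numerically integrates `y` over `x` with the trapezoidal rule. Used for all
#' area-under-curve (AUC) computations in the package so that MEG feature
#' areas and hemodynamic response areas are integrated consistently.
#'
#' @param x Numeric vector of sample locations (strictly increasing).
#' @param y Numeric vector of sample values, same length as `x`.
#' @return The signed integral as a scalar.
#' @export
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Order-4 Butterworth applied forwards and backwards (zero phase) so that
#' evoked-response latencies are preserved.
#'
#' @param x Numeric vector.
#' @param cutoff_hz -3 dB cutoff frequency in Hz.
#' @param fs Sampling frequency in Hz.
#' @param order Filter order before the forward-backward pass.
#' @return Filtered vector, same length as `x`.
#' @keywords internal
lowpass_zero_phase <- function(x, cutoff_hz, fs, order = 4) {
  w <- cutoff_hz / (fs / 2)
  if (w >= 1) return(x)
  bf <- signal::butter(order, w, type = "low")
  filtfilt_padded(bf, x, ceiling(3 * fs / cutoff_hz))
}

#' @rdname lowpass_zero_phase
#' @keywords internal
highpass_zero_phase <- function(x, cutoff_hz, fs, order = 2) {
  w <- cutoff_hz / (fs / 2)
  bf <- signal::butter(order, w, type = "high")
  filtfilt_padded(bf, x, ceiling(3 * fs / cutoff_hz))
}

#' Zero-phase notch filter (band-stop)
#' @keywords internal
notch_zero_phase <- function(x, freq_hz, fs, half_width_hz = 2, order = 2) {
  w <- c(freq_hz - half_width_hz, freq_hz + half_width_hz) / (fs / 2)
  if (any(w >= 1)) return(x)
  bf <- signal::butter(order, w, type = "stop")
  filtfilt_padded(bf, x, ceiling(3 * fs / half_width_hz))
}

# forward-backward filtering with mirror padding so that edge transients of
# the zero-state IIR passes fall on the padding, not on the data
filtfilt_padded <- function(bf, x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1)
  if (npad < 1) return(as.numeric(signal::filtfilt(bf, x)))
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(npad + 1):(npad + n)]
}

#' Decimate a uniformly sampled signal with anti-alias filtering
#'
#' Low-pass filters at 80% of the target Nyquist frequency (zero phase) and
#' keeps every `factor`-th sample, starting from the first, so that the
#' decimated time base is `t[1], t[1 + factor], ...`.
#'
#' @param x Numeric vector.
#' @param factor Integer decimation factor.
#' @param fs Original sampling frequency (Hz).
#' @return Numeric vector of length `ceiling(length(x) / factor)`.
#' @keywords internal
decimate_signal <- function(x, factor, fs) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(x)
  target_fs <- fs / factor
  y <- lowpass_zero_phase(x, 0.8 * target_fs / 2, fs, order = 4)
  y[seq(1, length(x), by = factor)]
}

#' Zero-phase Butterworth filtering of channel matrices via the FFT
#'
#' Applies the squared-magnitude Butterworth response (the frequency-domain
#' equivalent of a forward-backward IIR pass) to every column of `X` at
#' once. Columns are extended by their mirror image before the transform to
#' suppress circular edge effects.
#'
#' @param X Numeric matrix (time x channels) or vector.
#' @param fs Sampling frequency (Hz).
#' @param low,high Band corners in Hz (`NA` to skip the corresponding side;
#'   `low` = high-pass corner, `high` = low-pass corner).
#' @param order Butterworth order of each one-sided response.
#' @return Filtered matrix, same shape as `X`.
#' @keywords internal
fft_bandpass <- function(X, fs, low = NA, high = NA, order = 4) {
  vec <- is.null(dim(X))
  X <- as.matrix(X)
  n <- nrow(X)
  Xe <- rbind(X, X[n:1, , drop = FALSE])  # even extension
  m <- 2L * n
  f <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) * fs / m
  fa <- abs(f)
  H <- rep(1, m)
  if (!is.na(high)) H <- H / (1 + (fa / high)^(2 * order))
  if (!is.na(low)) {
    hp <- 1 - 1 / (1 + (fa / low)^(2 * order))
    H <- H * hp
  }
  Y <- Re(stats::mvfft(stats::mvfft(Xe) * H, inverse = TRUE)) / m
  out <- Y[seq_len(n), , drop = FALSE]
  if (vec) as.numeric(out) else out
}

#' Anti-aliased decimation of channel matrices
#'
#' FFT low-pass at 80% of the target Nyquist frequency, then keeps every
#' `factor`-th row starting at the first.
#' @keywords internal
decimate_matrix <- function(X, factor, fs) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(X)
  Y <- fft_bandpass(X, fs, high = 0.8 * (fs / factor) / 2, order = 4)
  if (is.null(dim(Y))) Y[seq(1, length(Y), by = factor)]
  else Y[seq(1, nrow(Y), by = factor), , drop = FALSE]
}

#' Block-mean decimation of channel matrices
#'
#' Averages each consecutive block of `factor` rows (trimming an incomplete
#' trailing block). The boxcar acts as the anti-alias filter; sample
#' timestamps refer to the first sample of each block.
#' @keywords internal
blockmean_decimate <- function(X, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(X)
  n <- (nrow(X) %/% factor) * factor
  m <- n %/% factor
  out <- matrix(0, m, ncol(X))
  for (k in seq_len(factor)) {
    out <- out + X[seq(k, n, by = factor), , drop = FALSE]
  }
  out / factor
}

#' Derive a child seed from a base seed
#'
#' Deterministic mixing of a base seed with a stream index, kept below 2^31
#' so the result is a valid R integer seed. Used to give every stage of the
#' pipeline its own reproducible random stream.
#'
#' @param seed Integer base seed.
#' @param stream Integer stream index.
#' @return An integer seed.
#' @export
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647L)
}
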