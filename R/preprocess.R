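#' Canonical EEG frequency bands
#'
#' Fixed conventional boundaries used whenever individualized bands are not
#' requested: delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30 Hz.
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
canonical_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

# --- windowed-sinc FIR design -----------------------------------------------

# Hamming-windowed sinc lowpass kernel; numtaps odd so the kernel is
# symmetric about an integer delay (exact zero-phase after compensation).
fir_lowpass_kernel <- function(fc, fs, numtaps) {
  if (numtaps %% 2 == 0) numtaps <- numtaps + 1
  m <- (numtaps - 1) / 2
  n <- seq(-m, m)
  h <- 2 * fc / fs * sinc_(2 * fc / fs * n)
  w <- 0.54 + 0.46 * cos(pi * n / m)
  h <- h * w
  h / sum(h)
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# taps for a Hamming window from the transition width (approx 3.3/df_norm)
fir_numtaps <- function(trans_hz, fs) {
  n <- ceiling(3.3 * fs / trans_hz)
  if (n %% 2 == 0) n <- n + 1
  max(n, 9L)
}

# Zero-phase application of a symmetric odd-length kernel: reflect-pad by the
# half-length, FFT convolution, take the centered part.  Works on a vector.
fir_apply_zerophase <- function(x, h) {
  m <- (length(h) - 1) / 2
  n <- length(x)
  pad <- min(m, n - 1)
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xe <- c(left, x, right)
  # linear convolution via FFT, 'same' part
  L <- length(xe) + length(h) - 1
  nfft <- stats::nextn(L, 2)
  y <- Re(fft(fft(c(xe, rep(0, nfft - length(xe)))) *
                fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE)) / nfft
  y <- y[(m + 1):(m + length(xe))]       # compensate group delay
  y[(pad + 1):(pad + n)]
}

apply_fir_recording <- function(rec, h) {
  out <- rec
  out$data <- t(apply(rec$data, 1, fir_apply_zerophase, h = h))
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) design, built as the difference of two lowpass
#' kernels; transition width 25% of the lower band edge with a 0.5 Hz floor.
#' Applied with reflective padding and group-delay compensation, so the net
#' phase shift is zero and a symmetric pulse keeps its center of mass.
#'
#' @param rec an [recording()].
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @return Filtered recording, same shape.
#' @export
bandpass_fir <- function(rec, lo = 0.5, hi = 45) {
  validate_recording(rec)
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi && hi < nyq))
    stop(sprintf("invalid band [%g, %g] Hz for fs = %g Hz", lo, hi, rec$fs))
  trans <- max(0.5, 0.25 * lo)
  numtaps <- fir_numtaps(trans, rec$fs)
  if (numtaps >= n_samples(rec))
    numtaps <- (n_samples(rec) %/% 2) * 2 - 1
  h_hi <- fir_lowpass_kernel(hi, rec$fs, numtaps)
  h_lo <- fir_lowpass_kernel(lo, rec$fs, numtaps)
  h <- h_hi - h_lo
  apply_fir_recording(rec, h)
}

#' Filter one recording into several bands
#'
#' @param rec an [recording()].
#' @param bands named list of `c(lo, hi)` pairs, e.g. [canonical_bands()].
#' @return Named list of filtered recordings, one per band.
#' @export
bandpass_bank <- function(rec, bands = canonical_bands()) {
  lapply(bands, function(b) bandpass_fir(rec, b[1], b[2]))
}

# --- IIR notch ---------------------------------------------------------------

# RBJ biquad notch coefficients
notch_biquad <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

iir_filter1 <- function(b, a, x) {
  v <- stats::filter(x, b, method = "convolution", sides = 1)
  v[is.na(v)] <- 0
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

# forward-backward IIR with reflective padding (zero net phase)
iir_filtfilt <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1, 1000L)
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xe <- c(left, x, right)
  y <- iir_filter1(b, a, xe)
  y <- rev(iir_filter1(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase narrowband notch filter
#'
#' Second-order IIR notch (Q = 30) applied forward and backward, rejecting
#' power-line interference at `freq` while leaving nearby frequencies nearly
#' untouched.
#'
#' @param rec an [recording()].
#' @param freq notch center in Hz (default 50, must be below Nyquist).
#' @param Q notch quality factor (center / -3 dB bandwidth).
#' @return Filtered recording, same shape.
#' @export
notch_filter <- function(rec, freq = 50, Q = 30) {
  validate_recording(rec)
  if (freq >= rec$fs / 2)
    stop(sprintf("notch frequency %g Hz is at or above Nyquist (%g Hz)",
                 freq, rec$fs / 2))
  co <- notch_biquad(freq, rec$fs, Q)
  out <- rec
  out$data <- t(apply(rec$data, 1, function(x) iir_filtfilt(co$b, co$a, x)))
  out
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous cross-channel mean from every channel, so each
#' sample's mean over channels becomes zero.  Idempotent.
#'
#' @param rec an [recording()] with at least two channels.
#' @return Re-referenced recording.
#' @export
rereference_average <- function(rec) {
  validate_recording(rec)
  if (n_channels(rec) < 2) stop("average reference needs >= 2 channels")
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  out
}

#' Standard preprocessing chain
#'
#' Notch, band-pass, average re-reference, in that order.
#'
#' @param rec an [recording()].
#' @param notch notch center in Hz, or `NULL` to skip.
#' @param band `c(lo, hi)` pass band in Hz, or `NULL` to skip.
#' @return Preprocessed recording.
#' @export
preprocess <- function(rec, notch = 50, band = c(0.5, 45)) {
  if (!is.null(notch) && notch < rec$fs / 2) rec <- notch_filter(rec, notch)
  if (!is.null(band)) rec <- bandpass_fir(rec, band[1], band[2])
  rereference_average(rec)
}
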