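#' Welch power spectral density
#'
#' Averaged modified periodograms: Hamming-windowed segments (default 2 s,
#' 50% overlap), one-sided density scaling in signal-units^2/Hz.
#'
#' @param rec an [recording()] (or a numeric vector with `fs` given).
#' @param fs sampling rate, taken from `rec` when it is a recording.
#' @param seg_len segment length in samples (default `2 * fs`).
#' @param overlap fractional overlap of consecutive segments.
#' @return `list(freq, psd)`: frequency grid (Hz) and channels x freq matrix.
#' @export
welch_psd <- function(rec, fs = NULL, seg_len = NULL, overlap = 0.5) {
  if (inherits(rec, "nf_recording")) {
    x <- rec$data
    fs <- rec$fs
  } else {
    x <- matrix(as.numeric(rec), nrow = 1)
    if (is.null(fs)) stop("fs required for plain-vector input")
  }
  n <- ncol(x)
  if (is.null(seg_len)) seg_len <- min(n, round(2 * fs))
  seg_len <- min(seg_len, n)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- hamming_window(seg_len)
  U <- sum(w^2)
  nfreq <- seg_len %/% 2 + 1L
  freq <- (seq_len(nfreq) - 1) * fs / seg_len
  psd <- matrix(0, nrow(x), nfreq)
  for (s in starts) {
    seg <- x[, s:(s + seg_len - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    segw <- sweep(seg, 2, w, `*`)
    sp <- t(apply(segw, 1, function(v) abs(fft(v)[seq_len(nfreq)])^2))
    if (nrow(x) == 1L) sp <- matrix(sp, nrow = 1)
    psd <- psd + sp
  }
  psd <- psd / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist when present)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (seg_len %% 2 == 0) dbl[nfreq] <- 1
  psd <- sweep(psd, 2, dbl, `*`)
  list(freq = freq, psd = psd)
}
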