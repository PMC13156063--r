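# internal numeric helpers shared across modules

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# derive a child seed, kept inside 32-bit signed range
child_seed <- function(seed, k) (as.numeric(seed) * 7919 + k * 104729) %% 2147483629

# Gaussian spectral-domain narrowband filter (FWHM in Hz) applied to a
# vector; operates on both spectral halves so the output is real.
gaussian_narrowband <- function(x, fs, f, fwhm) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)     # mirrored axis: |f| for both halves
  g <- exp(-4 * log(2) * (freqs - f)^2 / fwhm^2)
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

# 1/f^exponent noise by spectral shaping of white noise; unit SD output
one_over_f_noise <- function(n, exponent = 1, fs = 1) {
  w <- rnorm(n)
  W <- fft(w)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  shape <- ifelse(freqs > 0, freqs^(-exponent / 2), 0)
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

moving_average <- function(x, w) {
  if (w < 2) return(x)
  padL <- (w - 1) %/% 2
  padR <- w - 1 - padL
  xe <- c(rep(x[1], padL), x, rep(x[length(x)], padR))
  cs <- cumsum(xe)
  (cs[w:length(xe)] - c(0, cs[seq_len(length(xe) - w)])) / w
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# shift a series forward by `lag` samples (zero-padded at the start)
lag_shift <- function(x, lag) c(rep(0, lag), x[seq_len(length(x) - lag)])
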