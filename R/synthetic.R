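#' Specify a spatially coherent band-limited oscillation
#'
#' The oscillation carrier is Gaussian-spectral-filtered white noise centered
#' at `peak_freq` with spectral width `fwhm`; bands therefore have genuine
#' width rather than being spectral lines.  Spatial structure is partially
#' coherent: each channel receives `sqrt(coherence)` of a shared carrier
#' plus `sqrt(1 - coherence)` of a channel-private carrier at the same
#' spectral location, scaled by `amplitude_map`.  (A fully shared carrier
#' would be cancelled on mid-gain channels by average re-referencing.)
#' `sine_frac` mixes a pure sinusoid at the peak frequency into every
#' carrier (0 = pure filtered noise, 1 = pure tone); a higher fraction
#' yields a more regular, lower-complexity rhythm at unchanged spectral
#' location.
#'
#' @param peak_freq center frequency in Hz (> 0).
#' @param fwhm spectral full width at half maximum in Hz (> 0).
#' @param amplitude_map named or positional per-channel gain (unitless, >= 0);
#'   interpreted as the oscillation's SD in units of the 1/f noise SD.
#' @param sine_frac fraction in `[0, 1]` of a pure sinusoid in the carrier.
#' @param coherence fraction in `[0, 1]` of shared (spatially coherent)
#'   carrier variance; default 1 (a single rank-1 carrier, the regime the
#'   GED band detector is designed for).  Values below 1 add channel-private
#'   carrier variance at the same spectral location.
#' @param phase_seed optional integer decoupling this oscillation's carrier
#'   noise from the subject seed.
#' @return An `nf_oscillation` spec.
#' @export
oscillation_spec <- function(peak_freq, fwhm, amplitude_map,
                             sine_frac = 0, coherence = 1,
                             phase_seed = NULL) {
  if (peak_freq <= 0) stop("peak_freq must be > 0")
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (!any(amplitude_map > 0)) stop("at least one channel gain must be > 0")
  if (any(amplitude_map < 0)) stop("amplitude_map gains must be >= 0")
  if (coherence < 0 || coherence > 1) stop("coherence must be in [0, 1]")
  structure(list(peak_freq = peak_freq, fwhm = fwhm,
                 amplitude_map = amplitude_map, sine_frac = sine_frac,
                 coherence = coherence, phase_seed = phase_seed),
            class = "nf_oscillation")
}

#' Specify a planted directed lagged coupling between channels
#'
#' Ground truth for connectivity recovery.  Each coupling injects a
#' dedicated band-limited unit-SD "messenger" carrier: the source channel
#' receives the messenger itself, and the target channel receives
#' `strength * f(messenger(t - lag))` (f linear, quadratic, or threshold
#' exceedance).  A messenger private to the coupled pair is required for the
#' planted direction to be identifiable at all: a component shared at zero
#' lag (like the spatially coherent oscillation carriers) adds nothing to
#' the target's own past and is invisible to any Granger-type method.  When
#' `band` is given the messenger is narrowband in that band, making the
#' coupling band-specific.
#'
#' @param source,target channel labels (must differ).
#' @param lag lag in samples (>= 1).
#' @param strength unitless coupling gain.
#' @param form `"linear"`, `"quadratic"` or `"threshold"`.
#' @param band optional `c(lo, hi)` Hz restricting the coupled component.
#' @param fwhm spectral width of the messenger carrier; default half the
#'   band width (keeps tails in-band).
#' @return An `nf_coupling` spec.
#' @export
coupling_spec <- function(source, target, lag, strength,
                          form = c("linear", "quadratic", "threshold"),
                          band = NULL, fwhm = NULL) {
  form <- match.arg(form)
  if (identical(source, target)) stop("coupling source must differ from target")
  if (lag < 1) stop("coupling lag must be >= 1 sample")
  structure(list(source = source, target = target, lag = as.integer(lag),
                 strength = strength, form = form, band = band,
                 fwhm = fwhm),
            class = "nf_coupling")
}

coupling_fun <- function(form) {
  switch(form,
         linear = function(u) u,
         quadratic = function(u) u^2,
         threshold = function(u) as.numeric(u > quantile(u, 0.9)))
}

#' Specify one synthetic subject
#'
#' @param group group label, conventionally `"ASD-like"` or `"TD-like"`.
#' @param oscillations list of [oscillation_spec()].
#' @param couplings list of [coupling_spec()] (possibly empty).
#' @param noise_exponent 1/f spectral slope of the background noise.
#' @param noise_gain SD multiplier of the background noise.
#' @param duration recording length in seconds.
#' @param fs sampling rate in Hz (>= 100); `duration * fs` must be integer.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param labels channel labels (default the standard 8-channel montage).
#' @param meta extra metadata carried into the recording.
#' @return An `nf_subject_spec`.
#' @export
subject_spec <- function(group = "TD-like", oscillations = list(),
                         couplings = list(), noise_exponent = 1,
                         noise_gain = 1, duration = 60, fs = 250, seed = 1,
                         labels = nf_channels(), meta = list()) {
  if (duration <= 0 || fs <= 0) stop("duration and fs must be positive")
  if (fs < 100) stop("fs must be >= 100 Hz")
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9) stop("duration x fs must be an integer sample count")
  for (cp in couplings)
    if (!all(c(cp$source, cp$target) %in% labels))
      stop("coupling references unknown channel: ", cp$source, "->", cp$target)
  structure(list(group = group, oscillations = oscillations,
                 couplings = couplings, noise_exponent = noise_exponent,
                 noise_gain = noise_gain, duration = duration, fs = fs,
                 seed = as.integer(seed), labels = labels, meta = meta),
            class = "nf_subject_spec")
}

#' Generate one synthetic EEG subject
#'
#' Signal model per channel: sum over oscillations of a shared unit-SD
#' carrier scaled by the channel gain, plus planted coupling terms added to
#' target channels, plus unit-SD 1/f background noise scaled by
#' `noise_gain`.  Deterministic for a fixed spec seed.
#'
#' @param spec an [subject_spec()].
#' @return `list(recording, truth)`: the [recording()] and a ground-truth
#'   list with planted band intervals (peak +/- fwhm/2), the coupling edge
#'   list, and the generating spec.
#' @export
generate_subject <- function(spec) {
  stopifnot(inherits(spec, "nf_subject_spec"))
  n <- as.integer(round(spec$duration * spec$fs))
  nch <- length(spec$labels)
  with_seed(spec$seed, {
    osc_sig <- matrix(0, nch, n)
    for (k in seq_along(spec$oscillations)) {
      os <- spec$oscillations[[k]]
      chans <- if (is.null(os$phase_seed)) {
        make_carrier_set(n, nch, spec$fs, os)
      } else {
        with_seed(os$phase_seed, make_carrier_set(n, nch, spec$fs, os))
      }
      gains <- channel_gains(os$amplitude_map, spec$labels)
      osc_sig <- osc_sig + gains * chans
    }
    coup_sig <- matrix(0, nch, n)
    for (cp in spec$couplings) {
      si <- match(cp$source, spec$labels)
      ti <- match(cp$target, spec$labels)
      msg <- rnorm(n)
      if (!is.null(cp$band))
        msg <- gaussian_narrowband(msg, spec$fs, mean(cp$band),
                                   cp$fwhm %||% (diff(cp$band) / 2))
      msg <- standardize(msg)
      f <- coupling_fun(cp$form)
      coup_sig[si, ] <- coup_sig[si, ] + msg
      coup_sig[ti, ] <- coup_sig[ti, ] +
        cp$strength * standardize(f(lag_shift(msg, cp$lag)))
    }
    noise <- t(vapply(seq_len(nch), function(i)
      one_over_f_noise(n, spec$noise_exponent, spec$fs), numeric(n)))
    data <- osc_sig + coup_sig + spec$noise_gain * noise
  })
  meta <- c(list(group = spec$group, seed = spec$seed), spec$meta)
  rec <- recording(data, fs = spec$fs, labels = spec$labels, meta = meta)
  bands <- if (length(spec$oscillations)) {
    do.call(rbind, lapply(spec$oscillations, function(os)
      data.frame(peak = os$peak_freq, lo = os$peak_freq - os$fwhm / 2,
                 hi = os$peak_freq + os$fwhm / 2, fwhm = os$fwhm)))
  } else data.frame(peak = numeric(), lo = numeric(), hi = numeric(),
                    fwhm = numeric())
  edges <- if (length(spec$couplings)) {
    do.call(rbind, lapply(spec$couplings, function(cp)
      data.frame(source = cp$source, target = cp$target, lag = cp$lag,
                 strength = cp$strength, form = cp$form,
                 band_lo = if (is.null(cp$band)) NA_real_ else cp$band[1],
                 band_hi = if (is.null(cp$band)) NA_real_ else cp$band[2])))
  } else data.frame(source = character(), target = character(),
                    lag = integer(), strength = numeric(), form = character(),
                    band_lo = numeric(), band_hi = numeric())
  list(recording = rec, truth = list(bands = bands, couplings = edges,
                                     spec = spec))
}

make_carrier <- function(n, fs, os) {
  x <- standardize(gaussian_narrowband(rnorm(n), fs, os$peak_freq, os$fwhm))
  if (os$sine_frac > 0) {
    tone <- sqrt(2) * sin(2 * pi * os$peak_freq * seq_len(n) / fs +
                            runif(1, 0, 2 * pi))
    x <- standardize((1 - os$sine_frac) * x + os$sine_frac * tone)
  }
  x
}

# partially coherent channel set: sqrt(rho) shared + sqrt(1-rho) private
make_carrier_set <- function(n, nch, fs, os) {
  shared <- make_carrier(n, fs, os)
  rho <- os$coherence %||% 1
  if (rho >= 1) return(matrix(rep(shared, each = nch), nch))
  priv <- t(vapply(seq_len(nch), function(i) make_carrier(n, fs, os),
                   numeric(n)))
  sqrt(rho) * matrix(rep(shared, each = nch), nch) + sqrt(1 - rho) * priv
}

channel_gains <- function(amplitude_map, labels) {
  if (!is.null(names(amplitude_map))) {
    g <- setNames(rep(0, length(labels)), labels)
    g[names(amplitude_map)] <- amplitude_map
    unname(g)
  } else {
    if (length(amplitude_map) != length(labels))
      stop("amplitude_map length must match channel count")
    as.numeric(amplitude_map)
  }
}
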