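# small fixtures built in code at test time

tone_recording <- function(freqs, fs = 250, dur = 8, nch = 2, amp = 1,
                           noise = 0) {
  n <- dur * fs
  t <- seq_len(n) / fs
  sig <- rowSums(vapply(freqs, function(f) amp * sin(2 * pi * f * t),
                        numeric(n)))
  data <- matrix(rep(sig, each = nch), nrow = nch)
  if (noise > 0) data <- data + matrix(rnorm(nch * n, sd = noise), nch)
  recording(data, fs = fs, labels = paste0("ch", seq_len(nch)))
}

rms <- function(x) sqrt(mean(x^2))

# two-rhythm subject used by the gedBounds recovery tests: planted theta
# 5-7 Hz (central) and alpha 9-11 Hz (occipital) at SNR 3
two_rhythm_subject <- function(seed, fs = 250, dur = 60) {
  spec <- subject_spec(
    oscillations = list(
      oscillation_spec(6, 2, 3 * c(.7, .7, .5, 1.2, 1.2, .5, .8, .8)),
      oscillation_spec(10, 2, 3 * c(.4, .4, .5, .8, .8, .5, 1.5, 1.5))),
    noise_gain = 1, duration = dur, fs = fs, seed = seed)
  generate_subject(spec)
}
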