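#' Binarize a series at its median
#'
#' Values strictly greater than the median map to 1, all others (including
#' exact ties with the median) to 0.  Invariant under strictly monotone
#' increasing transforms of the input.
#'
#' @param series numeric vector, length >= 2.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize_median <- function(series) {
  if (length(series) < 2) stop("series must have length >= 2")
  as.integer(series > median(series))
}

#' Lempel-Ziv (LZ76) phrase count
#'
#' Exhaustive-history parsing by the Kaspar-Schuster scanning procedure:
#' the sequence is split left-to-right into the minimal number of phrases
#' such that each phrase (up to its final symbol) is reproducible from the
#' preceding history.
#'
#' @param bits integer/logical 0-1 vector.
#' @return Integer phrase count `c(n) >= 1`.
#' @export
lz76_count <- function(bits) {
  bits <- as.integer(bits)
  if (!length(bits)) stop("empty sequence")
  if (!all(bits %in% c(0L, 1L))) stop("sequence must be binary 0/1")
  lz76_count_cpp(bits)
}

#' Normalized Lempel-Ziv complexity
#'
#' `c(n) * log2(n) / n`, the standard binary-alphabet normalization: near 1
#' for i.i.d. fair-coin input as n grows, and small for regular sequences.
#'
#' @param bits integer/logical 0-1 vector, length >= 2.
#' @return Unitless complexity value.
#' @export
lzc_normalized <- function(bits) {
  n <- length(bits)
  if (n < 2) stop("sequence must have length >= 2")
  lz76_count(bits) * log2(n) / n
}

#' Per-channel, per-band Lempel-Ziv complexity features
#'
#' The recording is analyzed broadband and (optionally) within each band:
#' the signal is band-pass filtered, segmented into non-overlapping epochs
#' (default 4 s), each epoch binarized at its own median, and normalized LZC
#' averaged over epochs.
#'
#' @param rec a preprocessed [recording()], at least one epoch long.
#' @param bands named list of `c(lo, hi)` pairs, [canonical_bands()] by
#'   default; `NULL` for broadband only.  Pass individualized boundaries
#'   (e.g. from [gedbounds()]) to switch band definitions.
#' @param epoch_len epoch length in seconds.
#' @return Long-format data.frame (subject, band, channel, lzc) with the
#'   whole-brain per-band means in attribute `"global"`; band `"broadband"`
#'   rows are always present.
#' @export
lzc_features <- function(rec, bands = canonical_bands(), epoch_len = 4) {
  validate_recording(rec)
  if (n_samples(rec) < epoch_len * rec$fs)
    stop("recording shorter than one ", epoch_len, "-s epoch")
  subject <- rec$meta$subject %||% "subject"
  sets <- c(list(broadband = rec),
            if (length(bands)) bandpass_bank(rec, bands))
  out <- do.call(rbind, lapply(names(sets), function(bn) {
    ep <- epoch_recording(sets[[bn]], epoch_len, overlap = 0)
    vals <- apply(ep$epochs, 2, function(chan_ep) {
      # chan_ep: epochs x samples for one channel
      mean(apply(chan_ep, 1, function(x) lzc_normalized(binarize_median(x))))
    })
    data.frame(subject = subject, band = bn, channel = rec$labels, lzc = vals,
               row.names = NULL)
  }))
  glob <- aggregate(lzc ~ band, out, mean)
  attr(out, "global") <- glob
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
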