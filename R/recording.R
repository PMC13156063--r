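#' @useDynLib neurofuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate approx ar coef cor cov fft mad median na.omit
#'   pnorm predict psignrank pt qt quantile rbinom rnorm runif sd setNames
#'   t.test var wilcox.test
#' @importFrom utils head modifyList read.delim tail write.table
"_PACKAGE"

#' Standard 8-channel montage used throughout
#'
#' Frontal (F3, F4), temporal (T3, T4), central (C3, C4) and occipital
#' (O1, O2) electrodes of the 10-20 system.
#' @export
nf_channels <- function() c("F3", "F4", "T3", "C3", "C4", "T4", "O1", "O2")

#' Construct a multichannel EEG recording
#'
#' The basic container of the package: a channels x samples real matrix
#' (microvolts) with a sampling rate, channel labels and free-form metadata
#' (subject id, group label, demographics).
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of channel names, one per row of `data`.
#' @param meta named list of metadata (e.g. `subject`, `group`, `age`, `sex`).
#' @return An object of class `nf_recording`.
#' @export
recording <- function(data, fs, labels = NULL, meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(labels)) {
    labels <- if (nrow(data) == 8L) nf_channels() else paste0("ch", seq_len(nrow(data)))
  }
  rec <- structure(
    list(data = data, fs = fs, labels = as.character(labels), meta = meta),
    class = "nf_recording"
  )
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(is.matrix(rec$data), is.numeric(rec$data))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0)
    stop("fs must be a single positive number")
  if (nrow(rec$data) != length(rec$labels))
    stop(sprintf("label/row mismatch: %d labels for %d channels",
                 length(rec$labels), nrow(rec$data)))
  if (anyNA(rec$data)) stop("recording contains NA values")
  invisible(rec)
}

#' @export
print.nf_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$fs
  cat(sprintf("<nf_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$data), ncol(x$data), dur, x$fs))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.nf_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

#' Segment a recording into fixed-length epochs
#'
#' Epochs use half-open sample windows `[start, start + L)`; a trailing
#' partial epoch is discarded.  The number of epochs is
#' `1 + floor((T - L) / (L * (1 - overlap)))` for signal length `T` and
#' epoch length `L` in samples.
#'
#' @param rec an `nf_recording`.
#' @param epoch_len epoch length in seconds.
#' @param overlap fractional overlap between consecutive epochs, in `[0, 1)`.
#' @return An `nf_epochs` object: array `epochs x channels x samples` plus
#'   `fs`, `labels`, `epoch_len`, `overlap`.
#' @export
epoch_recording <- function(rec, epoch_len, overlap = 0) {
  validate_recording(rec)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  L <- round(epoch_len * rec$fs)
  if (L < 2) stop("epoch_len x fs must be >= 2 samples")
  T <- n_samples(rec)
  if (T < L) stop(sprintf("recording too short: %d samples < one %d-sample epoch", T, L))
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, T - L + 1L, by = step)
  arr <- array(0, dim = c(length(starts), n_channels(rec), L))
  for (i in seq_along(starts))
    arr[i, , ] <- rec$data[, starts[i]:(starts[i] + L - 1L), drop = FALSE]
  structure(
    list(epochs = arr, fs = rec$fs, labels = rec$labels,
         epoch_len = epoch_len, overlap = overlap, meta = rec$meta),
    class = "nf_epochs"
  )
}

#' @export
print.nf_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<nf_epochs> %d epochs x %d channels x %d samples (%g s, overlap %g)\n",
              d[1], d[2], d[3], x$epoch_len, x$overlap))
  invisible(x)
}

n_epochs <- function(ep) dim(ep$epochs)[1]
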