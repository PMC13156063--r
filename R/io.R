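#' Read a recording from disk
#'
#' Two on-disk forms are supported.  `tsv`: a tab-separated matrix, one row
#' per channel, a header row of channel labels and the sampling rate in a
#' leading `# fs=<Hz>` comment line (or given via `fs`).  `edf`: European
#' Data Format, 16-bit, read with the built-in minimal reader (channel order
#' preserved).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"edf"`.
#' @param fs sampling rate override, required for a TSV without a `# fs=` line.
#' @param meta metadata list attached to the result.
#' @return An [recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "tsv", "edf"), fs = NULL,
                           meta = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else "tsv"
  }
  if (format == "edf") read_edf(path, meta = meta) else read_recording_tsv(path, fs = fs, meta = meta)
}

read_recording_tsv <- function(path, fs = NULL, meta = list()) {
  lines <- readLines(path)
  fsline <- grep("^#\\s*fs\\s*=", lines, value = TRUE)
  if (length(fsline)) fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", fsline[1]))
  if (is.null(fs) || is.na(fs))
    stop("sampling rate unknown: no '# fs=<Hz>' line in ", path,
         " and no fs= argument given")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("parse error in ", path, ": no data rows")
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  lens <- lengths(body)
  if (length(unique(lens)) != 1L)
    stop("parse error in ", path, ": ragged rows (row ",
         which(lens != lens[1])[1] + 1L, " has ",
         lens[lens != lens[1]][1], " fields, expected ", lens[1], ")")
  if (length(body) != length(labels))
    stop("parse error in ", path, ": header has ", length(labels),
         " labels but file has ", length(body), " channel rows")
  mat <- do.call(rbind, lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(body[[i]]))
    if (anyNA(v))
      stop("parse error in ", path, ": non-numeric value in row ", i + 1L,
           ", field ", which(is.na(v))[1])
    v
  }))
  recording(mat, fs = fs, labels = labels, meta = meta)
}

#' Write a recording as a delimited-text matrix
#'
#' Dialect: a `# fs=<Hz>` comment line, a header row of channel labels, then
#' one row of samples per channel (channels x samples, as stored).
#'
#' @param rec an [recording()].
#' @param path output path.
#' @param digits significant digits kept (text round-trip precision).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 8) {
  validate_recording(rec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  writeLines(paste(rec$labels, collapse = "\t"), con)
  rows <- apply(signif(rec$data, digits), 1,
                function(r) paste(format(r, trim = TRUE, digits = digits,
                                         scientific = NA),
                                  collapse = "\t"))
  writeLines(rows, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal EDF (European Data Format, 16-bit) reader/writer.  No pre-installed
# package provides EDF in this stack; the format is fixed-layout ASCII headers
# plus little-endian int16 records, which is what is implemented here.  Only
# equal-rate continuous signals are supported (sufficient for resting EEG).

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(paste0(s, strrep(" ", width)), 1, width)
}

read_edf <- function(path, meta = list()) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  gethdr <- function(off, len) trimws(substr(hdr, off + 1, off + len))
  n_records <- as.integer(gethdr(236, 8))
  rec_dur <- as.numeric(gethdr(244, 8))
  ns <- as.integer(gethdr(252, 4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header in ", path)
  sig <- rawToChar(readBin(con, "raw", 256L * ns))
  # offsets within the signal header block (per EDF spec, cumulative):
  # label 16, transducer 80, phys_dim 8, phys_min 8, phys_max 8,
  # dig_min 8, dig_max 8, prefilter 80, samples_per_record 8, reserved 32
  offs <- c(label = 0, transducer = 16, phys_dim = 96, phys_min = 104,
            phys_max = 112, dig_min = 120, dig_max = 128, prefilter = 136,
            spr = 216, reserved = 224)
  sget <- function(name, len) {
    vapply(seq_len(ns), function(i) {
      off <- offs[[name]] * ns + (i - 1) * len
      trimws(substr(sig, off + 1, off + len))
    }, "")
  }
  labels <- sget("label", 16)
  phys_min <- as.numeric(sget("phys_min", 8))
  phys_max <- as.numeric(sget("phys_max", 8))
  dig_min <- as.numeric(sget("dig_min", 8))
  dig_max <- as.numeric(sget("dig_max", 8))
  spr <- as.integer(sget("spr", 8))
  if (length(unique(spr)) != 1L)
    stop("EDF with per-signal sampling rates not supported: ", path)
  fs <- spr[1] / rec_dur
  data <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little")
      scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      cols <- ((r - 1) * spr[i] + 1):(r * spr[i])
      data[i, cols] <- phys_min[i] + (v - dig_min[i]) * scale
    }
  }
  recording(data, fs = fs, labels = labels, meta = meta)
}

#' Write a recording to a 16-bit EDF file
#'
#' One-second data records; requires an integer sampling rate and trims the
#' signal to a whole number of seconds.  Intended for fixtures and export;
#' quantization to 16 bits over the per-channel physical range applies.
#'
#' @param rec an [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  validate_recording(rec)
  fs <- rec$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  ns <- n_channels(rec)
  n_records <- floor(n_samples(rec) / fs)
  if (n_records < 1) stop("recording shorter than one 1-s EDF record")
  x <- rec$data[, seq_len(n_records * fs), drop = FALSE]
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  same <- pmax_ - pmin_ < 1e-12
  pmax_[same] <- pmin_[same] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field("X", 80), edf_field("X", 80),
    edf_field("01.01.26", 8), edf_field("00.00.00", 8),
    edf_field(256 + 256 * ns, 8), edf_field("", 44),
    edf_field(n_records, 8), edf_field("1", 8), edf_field(ns, 4))
  writeBin(charToRaw(hdr), con)
  blocks <- list(
    vapply(rec$labels, edf_field, "", width = 16),
    rep(edf_field("", 80), ns),
    rep(edf_field("uV", 8), ns),
    vapply(sprintf("%.6g", pmin_), edf_field, "", width = 8),
    vapply(sprintf("%.6g", pmax_), edf_field, "", width = 8),
    rep(edf_field(dmin, 8), ns),
    rep(edf_field(dmax, 8), ns),
    rep(edf_field("", 80), ns),
    rep(edf_field(fs, 8), ns),
    rep(edf_field("", 32), ns))
  for (b in blocks) writeBin(charToRaw(paste(b, collapse = "")), con)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      v <- round((x[i, cols] - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                   (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(v, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
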