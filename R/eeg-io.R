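#' An EEG recording with seizure annotations
#'
#' Container for a multi-channel scalp EEG recording: a samples-by-channels
#' numeric matrix, its sampling rate, and the seizure onset times used to
#' derive preictal labels.
#'
#' @param signals numeric matrix, samples in rows, channels in columns
#'   (column names are channel labels), or a named list of equal-length
#'   numeric vectors.
#' @param sampling_rate sampling rate in Hz.
#' @param seizure_onsets seizure onset times in seconds from record start.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(signals, sampling_rate, seizure_onsets = numeric(0)) {
  if (is.list(signals) && !is.data.frame(signals)) {
    signals <- do.call(cbind, signals)
  }
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (nrow(signals) < 1L || anyNA(signals)) {
    abort("`signals` must be a non-empty numeric matrix without NAs")
  }
  if (is.null(colnames(signals))) {
    colnames(signals) <- paste0("ch", seq_len(ncol(signals)))
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number (Hz)")
  }
  duration <- nrow(signals) / sampling_rate
  onsets <- as.numeric(seizure_onsets)
  if (any(onsets < 0 | onsets > duration)) {
    warn("seizure onsets outside the record were clipped")
    onsets <- pmin(pmax(onsets, 0), duration)
  }
  structure(
    list(
      signals = signals,
      sampling_rate = sampling_rate,
      seizure_onsets = sort(onsets),
      duration = duration
    ),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record> %d channels x %d samples @ %g Hz (%.1f s), %d seizure(s)\n",
    ncol(x$signals), nrow(x$signals), x$sampling_rate, x$duration,
    length(x$seizure_onsets)
  ))
  invisible(x)
}

# Fixed-width ASCII field helpers for the EDF header.
edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}
edf_num <- function(raw, from, width, n = 1L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- rawToChar(raw[(from + (i - 1L) * width):(from + i * width - 1L)])
    out[i] <- suppressWarnings(as.numeric(trimws(s)))
  }
  out
}
edf_chr <- function(raw, from, width, n = 1L) {
  vapply(seq_len(n), function(i) {
    trimws(rawToChar(raw[(from + (i - 1L) * width):(from + i * width - 1L)]))
  }, character(1))
}

#' Read an EDF (16-bit) EEG file
#'
#' Minimal reader for the European Data Format: parses the ASCII header and
#' per-signal subheaders, decodes the little-endian 16-bit samples and
#' rescales them to physical units. All signals must share one sampling rate.
#' Seizure onsets are not part of plain EDF; supply them directly or via a
#' sidecar CSV with an `onset_s` column.
#'
#' @param path EDF file path.
#' @param seizure_onsets onset times in seconds, or `NULL` to look for a
#'   `<path>.onsets.csv` sidecar.
#' @return An [eeg_record()].
#' @export
read_edf <- function(path, seizure_onsets = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L) abort("not an EDF file: truncated header")
  n_records <- edf_num(hdr, 237L, 8L)
  rec_dur <- edf_num(hdr, 245L, 8L)
  ns <- as.integer(edf_num(hdr, 253L, 4L))
  if (is.na(ns) || ns < 1L) abort("not an EDF file: bad signal count")
  sh <- readBin(con, "raw", 256L * ns)
  off <- 1L
  labels <- edf_chr(sh, off, 16L, ns); off <- off + 16L * ns
  off <- off + 80L * ns # transducer
  off <- off + 8L * ns  # physical dimension
  phys_min <- edf_num(sh, off, 8L, ns); off <- off + 8L * ns
  phys_max <- edf_num(sh, off, 8L, ns); off <- off + 8L * ns
  dig_min <- edf_num(sh, off, 8L, ns); off <- off + 8L * ns
  dig_max <- edf_num(sh, off, 8L, ns); off <- off + 8L * ns
  off <- off + 80L * ns # prefiltering
  spr <- as.integer(edf_num(sh, off, 8L, ns))
  if (length(unique(spr)) != 1L) {
    abort("signals with differing sampling rates are not supported")
  }
  total <- n_records * sum(spr)
  dat <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(dat) < total) abort("EDF data shorter than the header declares")
  # records x (signal-major within record) -> samples x channels
  sig <- matrix(NA_real_, nrow = n_records * spr[1], ncol = ns)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (j in seq_len(ns)) {
    idx <- as.vector(outer(seq_len(spr[j]), (seq_len(n_records) - 1L) *
                             sum(spr), "+") + (j - 1L) * spr[j])
    sig[, j] <- (dat[idx] - dig_min[j]) * scale[j] + phys_min[j]
  }
  colnames(sig) <- make.unique(labels)
  if (is.null(seizure_onsets)) {
    sidecar <- paste0(path, ".onsets.csv")
    if (file.exists(sidecar)) {
      seizure_onsets <- readr::read_csv(sidecar,
                                        show_col_types = FALSE)$onset_s
    } else {
      seizure_onsets <- numeric(0)
    }
  }
  eeg_record(sig, sampling_rate = spr[1] / rec_dur,
             seizure_onsets = seizure_onsets)
}

#' Write an EEG record as EDF (16-bit)
#'
#' Companion writer to [read_edf()], mainly for building small synthetic EDF
#' files in examples and tests. Each channel is scaled to the full 16-bit
#' digital range over its own physical extremes. Data are chunked into 1 s
#' records; the signal is zero-padded to a whole number of records.
#'
#' @param record an [eeg_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$sampling_rate
  if (fs != round(fs)) abort("write_edf needs an integer sampling rate")
  sig <- record$signals
  ns <- ncol(sig)
  spr <- as.integer(fs)
  n_records <- ceiling(nrow(sig) / spr)
  pad <- n_records * spr - nrow(sig)
  if (pad > 0) sig <- rbind(sig, matrix(0, nrow = pad, ncol = ns))
  phys_min <- apply(sig, 2L, min)
  phys_max <- apply(sig, 2L, max)
  flat <- phys_max == phys_min
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  dig <- round(sweep(sweep(sig, 2L, phys_min), 2L,
                     (phys_max - phys_min) / (dig_max - dig_min), "/")) +
    dig_min
  hdr <- paste0(
    edf_field("0", 8L),
    edf_field("synthetic patient", 80L),
    edf_field("synthetic recording", 80L),
    edf_field("01.01.00", 8L),
    edf_field("00.00.00", 8L),
    edf_field(256L * (ns + 1L), 8L),
    edf_field("", 44L),
    edf_field(n_records, 8L),
    edf_field("1", 8L),
    edf_field(ns, 4L)
  )
  fmt_g <- function(x) edf_field(formatC(x, format = "g", digits = 7), 8L)
  sub <- paste0(
    paste(edf_field(colnames(sig), 16L), collapse = ""),
    paste(rep(edf_field("", 80L), ns), collapse = ""),
    paste(rep(edf_field("uV", 8L), ns), collapse = ""),
    paste(fmt_g(phys_min), collapse = ""),
    paste(fmt_g(phys_max), collapse = ""),
    paste(rep(edf_field(dig_min, 8L), ns), collapse = ""),
    paste(rep(edf_field(dig_max, 8L), ns), collapse = ""),
    paste(rep(edf_field("", 80L), ns), collapse = ""),
    paste(rep(edf_field(spr, 8L), ns), collapse = ""),
    paste(rep(edf_field("", 32L), ns), collapse = "")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(hdr, sub), con, eos = NULL)
  for (r in seq_len(n_records)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(dig[rows, ]), con, size = 2L, endian = "little")
  }
  if (length(record$seizure_onsets) > 0) {
    readr::write_csv(tibble(onset_s = record$seizure_onsets),
                     paste0(path, ".onsets.csv"))
  }
  invisible(path)
}
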