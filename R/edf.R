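# Minimal EDF (European Data Format) 16-bit I/O.
#
# Layout: a 256-byte ASCII fixed header, then ns * 256 bytes of per-signal
# ASCII header fields (each field stored for all signals consecutively), then
# data records of little-endian int16 samples, record-major and signal-major
# within a record. Physical values are recovered by the affine map
# phys = (dig - dig_min) * (phys_max - phys_min) / (dig_max - dig_min) + phys_min.
# Only continuous recordings with a common sampling rate across signals are
# supported, which is all the averaging/sonification chain consumes.

read_ascii_field <- function(con, nchars, n = 1) {
  vapply(seq_len(n), function(i) {
    raw <- readChar(con, nchars, useBytes = TRUE)
    trimws(raw)
  }, character(1))
}

#' Read an EDF file
#'
#' Reads a 16-bit EDF/EDF+C file into an [eeg_recording()]. All signals must
#' share one sampling rate; annotation channels ("EDF Annotations") are
#' dropped.
#'
#' @param path Path to the EDF file.
#' @return An [eeg_recording()] with amplitudes in the file's physical units
#'   (microvolts for EEG), channel order preserved.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) < 256) {
    stop("cannot parse EDF file (truncated header): ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  version <- read_ascii_field(con, 8)
  patient <- read_ascii_field(con, 80)
  recording <- read_ascii_field(con, 80)
  read_ascii_field(con, 8)  # start date
  read_ascii_field(con, 8)  # start time
  header_bytes <- suppressWarnings(as.integer(read_ascii_field(con, 8)))
  reserved <- read_ascii_field(con, 44)
  n_records <- suppressWarnings(as.integer(read_ascii_field(con, 8)))
  record_dur <- suppressWarnings(as.numeric(read_ascii_field(con, 8)))
  ns <- suppressWarnings(as.integer(read_ascii_field(con, 4)))
  if (is.na(ns) || is.na(n_records) || is.na(record_dur)) {
    stop("cannot parse EDF header of ", path, call. = FALSE)
  }
  if (ns < 1) stop("EDF file has zero signals: ", path, call. = FALSE)
  if (grepl("EDF+D", reserved, fixed = TRUE)) {
    stop("discontinuous EDF+D files are not supported: ", path, call. = FALSE)
  }

  labels <- read_ascii_field(con, 16, ns)
  read_ascii_field(con, 80, ns)  # transducer
  read_ascii_field(con, 8, ns)   # physical dimension
  phys_min <- as.numeric(read_ascii_field(con, 8, ns))
  phys_max <- as.numeric(read_ascii_field(con, 8, ns))
  dig_min <- as.numeric(read_ascii_field(con, 8, ns))
  dig_max <- as.numeric(read_ascii_field(con, 8, ns))
  read_ascii_field(con, 80, ns)  # prefiltering
  spr <- as.integer(read_ascii_field(con, 8, ns))
  read_ascii_field(con, 32, ns)  # reserved
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr))) {
    stop("cannot parse EDF signal headers of ", path, call. = FALSE)
  }

  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop("EDF file has zero data signals: ", path, call. = FALSE)
  if (length(unique(spr[keep] / record_dur)) != 1) {
    stop("signals with differing sampling rates are not supported: ", path,
         call. = FALSE)
  }
  fs <- spr[keep][1] / record_dur

  total_per_record <- sum(spr)
  raw <- readBin(con, "integer", n = n_records * total_per_record,
                 size = 2, signed = TRUE, endian = "little")
  if (length(raw) < n_records * total_per_record) {
    stop("EDF data section shorter than header declares: ", path,
         call. = FALSE)
  }

  offsets <- c(0, cumsum(spr))
  data <- matrix(0, nrow = sum(keep), ncol = n_records * spr[keep][1])
  row <- 0L
  for (s in seq_len(ns)) {
    if (!keep[s]) next
    row <- row + 1L
    idx <- as.vector(outer(seq_len(spr[s]) + offsets[s],
                           (seq_len(n_records) - 1) * total_per_record, `+`))
    dig <- raw[idx]
    scale <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    data[row, ] <- (dig - dig_min[s]) * scale + phys_min[s]
  }
  eeg_recording(data, fs = fs, channel_labels = labels[keep],
                subject_id = patient)
}

fmt_edf_num <- function(x, width = 8) {
  s <- formatC(x, digits = width - 1, width = width, format = "g", flag = "-")
  s <- substr(gsub(" ", "", s), 1, width)
  if (abs(as.numeric(s) - x) > 1e-4 * max(1, abs(x))) {
    s <- substr(formatC(signif(x, 6), format = "fg", flag = "-"), 1, width)
  }
  s
}

pad_field <- function(x, width) {
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write an EDF file
#'
#' Writes an [eeg_recording()] as 16-bit EDF using one-second data records;
#' the recording is truncated to a whole number of seconds. Amplitudes are
#' mapped onto the full +/-32767 digital range, so quantisation error is
#' bounded by `max(abs(data)) / 32767` per sample.
#'
#' @param eeg An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_recording"))
  fs <- eeg$fs
  if (fs != round(fs)) stop("write_edf needs an integer sampling rate", call. = FALSE)
  n_records <- floor(ncol(eeg$data) / fs)
  if (n_records < 1) stop("recording shorter than one second", call. = FALSE)
  data <- eeg$data[, seq_len(n_records * fs), drop = FALSE]
  ns <- nrow(data)

  pmax_ <- max(abs(data), 1e-9)
  phys_min <- -pmax_
  phys_max <- pmax_
  dig_min <- -32767L
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)

  wr("0", 8)
  wr(eeg$subject_id, 80)
  wr("vibrotrace", 80)
  wr("01.01.26", 8)
  wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8)
  wr("", 44)
  wr(as.character(n_records), 8)
  wr("1", 8)
  wr(as.character(ns), 4)

  for (l in eeg$channel_labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(fmt_edf_num(phys_min), 8)
  for (i in seq_len(ns)) wr(fmt_edf_num(phys_max), 8)
  for (i in seq_len(ns)) wr(as.character(dig_min), 8)
  for (i in seq_len(ns)) wr(as.character(dig_max), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)

  # the affine map must use the *written* 8-char physical extrema
  wmin <- as.numeric(fmt_edf_num(phys_min))
  wmax <- as.numeric(fmt_edf_num(phys_max))
  scale <- (dig_max - dig_min) / (wmax - wmin)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      dig <- as.integer(round((data[s, cols] - wmin) * scale + dig_min))
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
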