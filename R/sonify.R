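#' Audio waveform container
#'
#' Mono amplitude series in [-1, 1] at an audio sampling rate, with bit-depth
#' metadata for PCM rendering.
#'
#' @param samples Numeric vector in [-1, 1].
#' @param fs_audio Sampling rate in Hz (default 44100).
#' @param bit_depth PCM bit depth (default 16).
#' @return An object of class `audio_waveform` with a `duration` element
#'   (seconds).
#' @export
audio_waveform <- function(samples, fs_audio = 44100, bit_depth = 16L) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("audio samples must be finite", call. = FALSE)
  if (fs_audio <= 0) stop("`fs_audio` must be > 0", call. = FALSE)
  if (max(abs(samples), 0) > 1 + 1e-12) {
    stop("audio samples must lie in [-1, 1]; normalize first", call. = FALSE)
  }
  structure(
    list(samples = samples, fs_audio = fs_audio, bit_depth = as.integer(bit_depth),
         duration = length(samples) / fs_audio),
    class = "audio_waveform"
  )
}

#' @export
print.audio_waveform <- function(x, ...) {
  cat(sprintf("<audio_waveform> %.2f s @ %g Hz, %d-bit (%d samples)\n",
              x$duration, x$fs_audio, x$bit_depth, length(x$samples)))
  invisible(x)
}

#' Mix EEG channels to a mono series
#'
#' @param eeg An [eeg_recording()].
#' @param mode `"mean"` for the per-sample arithmetic mean across channels,
#'   or a channel label to take that channel verbatim.
#' @return Numeric vector (one amplitude per sample, microvolts).
#' @export
mix_channels <- function(eeg, mode = "mean") {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (nrow(eeg$data) == 0 || ncol(eeg$data) == 0) {
    stop("empty recording", call. = FALSE)
  }
  if (identical(mode, "mean")) {
    colMeans(eeg$data)
  } else {
    if (!mode %in% eeg$channel_labels) {
      stop("unknown channel label: ", mode, call. = FALSE)
    }
    as.numeric(eeg$data[mode, ])
  }
}

#' Peak-normalize a mono series
#'
#' Scales the series so its peak magnitude equals `headroom`, preventing
#' saturation/clipping on PCM rendering. An all-zero series is returned
#' unchanged.
#'
#' @param series Finite numeric vector.
#' @param headroom Target peak magnitude in (0, 1]; default 0.99.
#' @return Scaled numeric vector of the same length.
#' @export
normalize_amplitude <- function(series, headroom = 0.99) {
  if (!all(is.finite(series))) stop("series contains non-finite values", call. = FALSE)
  if (headroom <= 0 || headroom > 1) stop("`headroom` must be in (0, 1]", call. = FALSE)
  peak <- max(abs(series))
  if (peak == 0) return(series)
  series * (headroom / peak)
}

# best rational approximation p/q to x with q <= max_den (continued fractions)
rational_approx <- function(x, max_den = 10000L) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12 * x) break
    frac <- r - a
    if (frac < 1e-12) break
    r <- 1 / frac
  }
  c(p = p1, q = q1)
}

#' Resample a mono series onto the audio grid
#'
#' Direct-mapping sonification: amplitudes are mapped linearly to sound
#' pressure with no frequency modulation or spectral transformation; the only
#' operation is band-limited (polyphase FIR) resampling onto the audio rate.
#' `time_scale` compresses the time base: the output lasts
#' `input duration / time_scale` seconds, so a signal's frequencies are
#' multiplied by `time_scale` on playback.
#'
#' @param series Mono numeric series.
#' @param fs_in Input sampling rate in Hz.
#' @param fs_audio Output audio rate in Hz (default 44100).
#' @param time_scale Positive time-compression factor. The default 2.7
#'   maps a 13.5 min EEG onto about five minutes of audio, the duration
#'   relation of the reference recordings.
#' @return An [audio_waveform()]. The samples are not normalized here; run
#'   [normalize_amplitude()] first (values are clipped to [-1, 1] as a
#'   safety net against interpolation overshoot).
#' @export
resample_to_audio <- function(series, fs_in, fs_audio = 44100, time_scale = 2.7) {
  if (fs_in <= 0 || fs_audio <= 0) stop("sampling rates must be > 0", call. = FALSE)
  if (time_scale <= 0) stop("`time_scale` must be > 0", call. = FALSE)
  ratio <- fs_audio / (fs_in * time_scale)
  n_out <- floor(length(series) * ratio)
  if (n_out < 2) stop("output would be shorter than 2 samples", call. = FALSE)
  if (abs(ratio - 1) < 1e-12) {
    out <- series
  } else {
    pq <- rational_approx(ratio)
    out <- signal::resample(series, pq["p"], pq["q"])
  }
  out <- pmin(pmax(out, -1), 1)
  audio_waveform(out, fs_audio = fs_audio)
}

#' Sonify an EEG recording
#'
#' Full direct-mapping chain: channel mixing, peak normalization, and
#' band-limited resampling to the audio rate.
#'
#' @inheritParams mix_channels
#' @inheritParams normalize_amplitude
#' @inheritParams resample_to_audio
#' @return An [audio_waveform()].
#' @export
sonify_eeg <- function(eeg, mode = "mean", headroom = 0.99,
                       fs_audio = 44100, time_scale = 2.7) {
  series <- normalize_amplitude(mix_channels(eeg, mode), headroom)
  w <- resample_to_audio(series, fs_in = eeg$fs, fs_audio = fs_audio,
                         time_scale = time_scale)
  # resampling can overshoot the headroom slightly; renormalize to contract
  w$samples <- normalize_amplitude(w$samples, headroom)
  w
}

#' Write / read a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE I/O: mono, 16-bit little-endian PCM. A write/read
#' round trip recovers every sample within 1/32768.
#'
#' @param w An [audio_waveform()] with samples in [-1, 1].
#' @param path File path.
#' @return `write_wav` returns `path` invisibly; `read_wav` returns an
#'   [audio_waveform()].
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "audio_waveform"))
  if (max(abs(w$samples), 0) > 1) stop("samples exceed [-1, 1]", call. = FALSE)
  pcm <- as.integer(round(w$samples * 32767))
  pcm <- pmin(pmax(pcm, -32768L), 32767L)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # PCM
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(w$fs_audio), con, size = 4, endian = "little")
  writeBin(as.integer(w$fs_audio * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                  # block align
  writeBin(16L, con, size = 2, endian = "little")                 # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4, useBytes = TRUE) != "RIFF") {
    stop("not a RIFF file: ", path, call. = FALSE)
  }
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") {
    stop("not a WAVE file: ", path, call. = FALSE)
  }
  fs <- NULL; bits <- NULL; channels <- NULL; pcm <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("only PCM WAV supported: ", path, call. = FALSE)
      channels <- fmt[2]
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV (data before fmt): ", path, call. = FALSE)
      if (bits != 16) stop("only 16-bit WAV supported: ", path, call. = FALSE)
      pcm <- readBin(con, "integer", n = size / 2, size = 2, signed = TRUE,
                     endian = "little")
      break
    } else {
      readBin(con, "raw", n = size + size %% 2)
    }
  }
  if (is.null(pcm)) stop("no data chunk in WAV file: ", path, call. = FALSE)
  if (channels != 1) stop("only mono WAV supported: ", path, call. = FALSE)
  audio_waveform(pmax(pcm / 32767, -1), fs_audio = fs, bit_depth = 16L)
}
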