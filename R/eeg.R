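#' Multichannel EEG recording
#'
#' The basic container for resting-state EEG: a channels x samples matrix of
#' amplitudes in microvolts, with a sampling rate and ordered channel labels
#' (10-20 montage names for scalp EEG).
#'
#' @param data Numeric matrix, channels x samples, finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Unique channel names, one per row of `data`.
#' @param subject_id Opaque subject identifier.
#' @param group_label One of `"AD"`, `"NC"`, `"none"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          subject_id = "", group_label = "none") {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("EEG data must be a finite numeric matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("need one channel label per data row", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  group_label <- match.arg(group_label, c("none", "AD", "NC"))
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         subject_id = as.character(subject_id), group_label = group_label),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (x$group_label != "none") paste0(" [", x$group_label, "]") else ""))
  invisible(x)
}

#' Standard 19-channel 10-20 montage labels
#' @return Character vector of 19 electrode names.
#' @export
montage_10_20 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Read an EEG recording from disk
#'
#' @param path File path.
#' @param format `"edf"` for 16-bit EDF/EDF+C, or `"matrix"` for the
#'   plain-text channel-matrix format written by [write_eeg_matrix()]
#'   (one `# fs=<Hz>` comment line, then one `label,v1,v2,...` row per
#'   channel).
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("edf", "matrix")) {
  format <- match.arg(format)
  switch(format, edf = read_edf(path), matrix = read_eeg_matrix(path))
}

#' @rdname read_eeg
#' @param eeg An [eeg_recording()] to write.
#' @export
write_eeg_matrix <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", eeg$fs), con)
  for (i in seq_len(nrow(eeg$data))) {
    writeLines(paste(c(eeg$channel_labels[i],
                       format(eeg$data[i, ], digits = 17)), collapse = ","),
               con)
  }
  invisible(path)
}

#' @rdname read_eeg
#' @export
read_eeg_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty channel-matrix file: ", path, call. = FALSE)
  fs_line <- grepl("^#\\s*fs=", lines)
  if (!any(fs_line)) stop("missing `# fs=` line in ", path, call. = FALSE)
  fs <- as.numeric(sub("^#\\s*fs=", "", lines[which(fs_line)[1]]))
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0) stop("no channels in ", path, call. = FALSE)
  parts <- strsplit(body, ",", fixed = TRUE)
  labels <- vapply(parts, `[[`, character(1), 1)
  rows <- lapply(parts, function(p) as.numeric(p[-1]))
  nlen <- unique(lengths(rows))
  if (length(nlen) != 1) stop("ragged channel rows in ", path, call. = FALSE)
  data <- do.call(rbind, rows)
  if (anyNA(data)) stop("cannot parse numeric samples in ", path, call. = FALSE)
  eeg_recording(data, fs = fs, channel_labels = labels)
}

#' Group-average EEG in the time domain
#'
#' Averages several subjects' recordings channel by channel in the time
#' domain, with no filtering, yielding one synthetic recording representative
#' of the group. Channels are aligned by label (EDF channel order may vary);
#' recordings of unequal length are truncated to the shortest common length
#' before averaging.
#'
#' @param recordings List of [eeg_recording()] objects with identical
#'   sampling rates and identical channel label sets.
#' @return An [eeg_recording()]; `group_label` is propagated when uniform
#'   across inputs.
#' @export
group_average <- function(recordings) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  if (length(recordings) < 1) stop("need at least one recording", call. = FALSE)
  stopifnot(all(vapply(recordings, inherits, logical(1), "eeg_recording")))
  fs <- unique(vapply(recordings, `[[`, numeric(1), "fs"))
  if (length(fs) != 1) {
    stop("recordings have mismatched sampling rates: ",
         paste(fs, collapse = ", "), call. = FALSE)
  }
  ref_labels <- recordings[[1]]$channel_labels
  for (r in recordings) {
    if (!setequal(r$channel_labels, ref_labels)) {
      stop("recordings have mismatched channel sets", call. = FALSE)
    }
  }
  n <- min(vapply(recordings, function(r) ncol(r$data), integer(1)))
  acc <- matrix(0, nrow = length(ref_labels), ncol = n)
  for (r in recordings) {
    acc <- acc + r$data[ref_labels, seq_len(n), drop = FALSE]
  }
  groups <- unique(vapply(recordings, `[[`, character(1), "group_label"))
  eeg_recording(acc / length(recordings), fs = fs,
                channel_labels = ref_labels,
                subject_id = paste0("group-average-n", length(recordings)),
                group_label = if (length(groups) == 1) groups else "none")
}

#' Synthetic EEG spectral profile
#'
#' Describes a group-level EEG spectrum as relative power weights over the
#' canonical bands (delta 0.5-4, theta 4-8, alpha centred on `alpha_peak_hz`,
#' beta 13-30, gamma 30-45 Hz) plus a broadband 1/f floor. The two presets
#' emulate the group-level contrast between Alzheimer's disease and healthy
#' controls: `"ad"` has elevated slow-band (delta/theta) and reduced
#' alpha/beta power; `"nc"` has a dominant ~10 Hz alpha peak.
#'
#' @param preset `"ad"`, `"nc"`, or `"custom"` (then supply `band_powers`).
#' @param band_powers Named nonnegative weights for
#'   `c(delta, theta, alpha, beta, gamma)`; normalised to sum 1.
#' @param alpha_peak_hz Centre of the alpha component in Hz.
#' @param noise_floor Relative power weight of broadband 1/f noise.
#' @param seed Default RNG seed carried by the profile.
#' @return An object of class `synth_profile`.
#' @export
synth_profile <- function(preset = c("custom", "ad", "nc"),
                          band_powers = NULL, alpha_peak_hz = 10,
                          noise_floor = 0.20, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(band_powers)) {
    band_powers <- switch(preset,
      # slow-band dominated: (delta+theta)/alpha = 5
      ad = c(delta = 0.35, theta = 0.25, alpha = 0.12, beta = 0.06, gamma = 0.02),
      # alpha dominated: clear ~10 Hz peak
      nc = c(delta = 0.10, theta = 0.10, alpha = 0.45, beta = 0.12, gamma = 0.03),
      custom = c(delta = 0.2, theta = 0.2, alpha = 0.2, beta = 0.2, gamma = 0.2)
    )
  }
  need <- c("delta", "theta", "alpha", "beta", "gamma")
  if (!all(need %in% names(band_powers))) {
    stop("`band_powers` must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  band_powers <- band_powers[need]
  if (any(band_powers < 0) || noise_floor < 0) {
    stop("power weights must be nonnegative", call. = FALSE)
  }
  tot <- sum(band_powers)
  if (tot <= 0) stop("at least one band weight must be positive", call. = FALSE)
  structure(
    list(band_powers = band_powers / tot, alpha_peak_hz = alpha_peak_hz,
         noise_floor = noise_floor, seed = as.integer(seed),
         preset = preset),
    class = "synth_profile"
  )
}

band_edges <- function(profile, fs) {
  ap <- profile$alpha_peak_hz
  nyq <- fs / 2
  clip <- function(lo, hi) c(max(lo, 0.25), min(hi, nyq * 0.98))
  list(delta = clip(0.5, 4), theta = clip(4, 8),
       alpha = clip(ap - 2, ap + 2), beta = clip(13, 30),
       gamma = clip(30, 45))
}

# Broadband 1/f (power) noise, band-limited to [f_lo, f_hi] Hz. The high
# cut emulates the upstream cleaning of resting EEG (band-passed recordings
# carry essentially no power above the low gamma range); without it the
# floor would extend to Nyquist, which no cleaned scalp EEG does.
one_over_f_noise <- function(n, fs, f_lo = 0.5, f_hi = 45) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, n - 1) / n
  f <- pmin(f, 1 - f) * fs # two-sided frequency magnitude, Hz
  shape <- 1 / sqrt(pmax(f, f_lo))
  shape[f < f_lo / 2 | f > min(f_hi, fs / 2)] <- 0
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y <- y / s
  y
}

#' Generate synthetic multichannel EEG
#'
#' Each channel is an independent sum of band-limited Gaussian noise
#' components (4th-order Butterworth band-pass applied to white noise, one
#' component per band, unit variance before weighting; a single filter pass
#' suffices since the phase response of a stochastic component is
#' immaterial) with
#' amplitude weights `sqrt(band_powers)` so that component *power* follows
#' the profile, plus a 1/f broadband floor weighted by
#' `sqrt(noise_floor)`. The result is scaled to a physiological RMS of
#' `target_sd` microvolts. Fully deterministic given `seed`; the global RNG
#' state is left untouched.
#'
#' @param profile A [synth_profile()].
#' @param n_channels Number of channels (19 gives the standard 10-20 montage
#'   labels).
#' @param duration Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed RNG seed; defaults to the profile's.
#' @param target_sd Per-channel output standard deviation in microvolts.
#' @param group_label Label stamped on the recording.
#' @return An [eeg_recording()].
#' @export
synth_eeg <- function(profile, n_channels = 19, duration = 60, fs = 500,
                      seed = profile$seed, target_sd = 20,
                      group_label = "none") {
  stopifnot(inherits(profile, "synth_profile"))
  if (duration <= 0 || fs <= 0) {
    stop("`duration` and `fs` must be positive", call. = FALSE)
  }
  n <- round(duration * fs)
  if (n < 2) stop("need at least 2 samples (duration * fs >= 2)", call. = FALSE)
  if (profile$alpha_peak_hz <= 0 || profile$alpha_peak_hz >= fs / 2) {
    stop("`alpha_peak_hz` must lie in (0, fs/2)", call. = FALSE)
  }
  edges <- band_edges(profile, fs)
  filters <- lapply(edges, function(e) {
    signal::butter(4, c(e[1], e[2]) / (fs / 2), type = "pass")
  })
  labels <- if (n_channels == 19) montage_10_20() else paste0("ch", seq_len(n_channels))
  data <- withr::with_seed(seed, {
    t(vapply(seq_len(n_channels), function(ch) {
      y <- numeric(n)
      for (b in names(profile$band_powers)) {
        w <- profile$band_powers[[b]]
        if (w <= 0) next
        comp <- as.numeric(signal::filter(filters[[b]], stats::rnorm(n)))
        s <- stats::sd(comp)
        if (s > 0) y <- y + sqrt(w) * comp / s
      }
      if (profile$noise_floor > 0) {
        y <- y + sqrt(profile$noise_floor) * one_over_f_noise(n, fs)
      }
      y
    }, numeric(n)))
  })
  s <- stats::sd(as.vector(data))
  if (s > 0) data <- data * (target_sd / s)
  eeg_recording(data, fs = fs, channel_labels = labels,
                subject_id = sprintf("synth-%s-seed%d", profile$preset, seed),
                group_label = group_label)
}
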