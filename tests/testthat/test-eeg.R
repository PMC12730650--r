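# EEG containers, file I/O, time-domain group averaging and the synthetic
# group-profile generator.

test_that("channel-matrix format round-trips exactly", {
  eeg <- toy_eeg(matrix(c(1.5, -2, 0, 4.25, 1e-3, 7), nrow = 2, byrow = TRUE),
                 fs = 500, labels = c("Fp1", "Fp2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_eeg_matrix(eeg, path)
  back <- read_eeg(path, format = "matrix")
  expect_identical(back$data, eeg$data)
  expect_identical(back$fs, 500)
  expect_identical(back$channel_labels, c("Fp1", "Fp2"))
})

test_that("EDF round trip recovers 19-channel data within 16-bit quantisation", {
  set.seed(11)
  data <- matrix(rnorm(19 * 1000, sd = 30), nrow = 19)
  eeg <- eeg_recording(data, fs = 500, channel_labels = montage_10_20(),
                       subject_id = "subj-01")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(eeg, path)
  back <- read_edf(path)
  expect_identical(back$channel_labels, montage_10_20())
  expect_equal(back$fs, 500)
  expect_equal(ncol(back$data), 1000)
  lsb <- max(abs(data)) / 32767
  expect_lt(max(abs(back$data - data[, 1:1000])), 1.01 * lsb)
})

test_that("EDF writer output is readable by an independent implementation", {
  # MNE-Python's EDF reader is a fully independent implementation of the
  # same published format; agreement validates both sides.
  py <- Sys.which("python")
  set.seed(7)
  data <- matrix(rnorm(3 * 200, sd = 25), nrow = 3)
  eeg <- eeg_recording(data, fs = 100, channel_labels = c("C3", "Cz", "C4"))
  edf <- withr::local_tempfile(fileext = ".edf")
  ref <- withr::local_tempfile(fileext = ".csv")
  write_edf(eeg, edf)
  utils::write.table(data, ref, row.names = FALSE, col.names = FALSE, sep = ",")
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "import mne",
    "raw = mne.io.read_raw_edf(sys.argv[1], preload=True, verbose='ERROR')",
    "got = raw.get_data() * 1e6  # MNE converts microvolts to volts",
    "ref = np.loadtxt(sys.argv[2], delimiter=',')",
    "print(float(np.abs(got - ref).max()))"
  ), script)
  out <- suppressWarnings(system2(py, c(script, edf, ref),
                                  stdout = TRUE, stderr = FALSE))
  maxdiff <- as.numeric(utils::tail(out, 1))
  lsb <- max(abs(data)) / 32767
  expect_lt(maxdiff, 2 * lsb)
})

test_that("degenerate EEG files raise parse errors naming the file", {
  empty <- withr::local_tempfile(fileext = ".edf")
  file.create(empty)
  expect_error(read_edf(empty), basename(empty))
  expect_error(read_edf("no-such-file.edf"), "not found")
  blank <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), blank)
  expect_error(read_eeg_matrix(blank), "empty")
})

test_that("group averaging is an elementwise mean with label alignment", {
  x <- toy_eeg(matrix(1:8, nrow = 2, byrow = TRUE), labels = c("A", "B"))
  expect_equal(group_average(list(x, x, x))$data, x$data)

  neg <- toy_eeg(-matrix(1:8, nrow = 2, byrow = TRUE), labels = c("A", "B"))
  expect_true(all(group_average(list(x, neg))$data == 0))

  a <- toy_eeg(matrix(c(1, 2, 3, 4, 10, 20, 30, 40), nrow = 2, byrow = TRUE),
               labels = c("A", "B"))
  b <- toy_eeg(matrix(c(5, 6, 7, 8, 50, 60, 70, 80), nrow = 2, byrow = TRUE),
               labels = c("A", "B"))
  avg <- group_average(list(a, b))
  expect_equal(unname(avg$data),
               matrix(c(3, 4, 5, 6, 30, 40, 50, 60), nrow = 2, byrow = TRUE))

  # channel order differs; alignment is by label, not index
  b_shuffled <- toy_eeg(b$data[c("B", "A"), ], labels = c("B", "A"))
  expect_equal(group_average(list(a, b_shuffled))$data, avg$data)
})

test_that("group averaging truncates to the shortest common length", {
  a <- toy_eeg(matrix(1:10, nrow = 1), labels = "A")
  b <- toy_eeg(matrix(rep(3, 6), nrow = 1), labels = "A")
  avg <- group_average(list(a, b))
  expect_equal(ncol(avg$data), 6)
  expect_equal(unname(avg$data[1, ]), (1:6 + 3) / 2)
})

test_that("group averaging is permutation invariant and bounded by extremes", {
  set.seed(42)
  recs <- lapply(1:4, function(i) {
    toy_eeg(matrix(rnorm(3 * 50), nrow = 3), labels = c("A", "B", "C"))
  })
  avg1 <- group_average(recs)
  avg2 <- group_average(recs[c(3, 1, 4, 2)])
  # equal up to summation-order rounding
  expect_equal(avg1$data, avg2$data, tolerance = 1e-12)

  lo <- Reduce(pmin, lapply(recs, `[[`, "data"))
  hi <- Reduce(pmax, lapply(recs, `[[`, "data"))
  expect_true(all(avg1$data >= lo - 1e-12) && all(avg1$data <= hi + 1e-12))

  # averaging n copies of one recording is the identity to fp tolerance
  expect_equal(group_average(recs[c(1, 1, 1)])$data, recs[[1]]$data,
               tolerance = 1e-12)
})

test_that("incompatible recordings are rejected", {
  a <- toy_eeg(matrix(1:4, nrow = 1), fs = 500, labels = "A")
  b <- toy_eeg(matrix(1:4, nrow = 1), fs = 250, labels = "A")
  expect_error(group_average(list(a, b)), "sampling rates")
  c2 <- toy_eeg(matrix(1:4, nrow = 1), fs = 500, labels = "Z")
  expect_error(group_average(list(a, c2)), "channel sets")
  expect_error(group_average(list()), "at least one")
})

test_that("group label propagates only when uniform", {
  a <- toy_eeg(matrix(1:4, nrow = 1), labels = "A", group = "AD")
  b <- toy_eeg(matrix(5:8, nrow = 1), labels = "A", group = "AD")
  expect_equal(group_average(list(a, b))$group_label, "AD")
  c2 <- toy_eeg(matrix(5:8, nrow = 1), labels = "A", group = "NC")
  expect_equal(group_average(list(a, c2))$group_label, "none")
})

test_that("synthetic EEG is deterministic in the seed and leaves the RNG alone", {
  pr <- synth_profile("nc", seed = 5)
  set.seed(123); before <- .Random.seed
  e1 <- synth_eeg(pr, n_channels = 3, duration = 2, fs = 250)
  expect_identical(.Random.seed, before)
  e2 <- synth_eeg(pr, n_channels = 3, duration = 2, fs = 250)
  expect_identical(e1$data, e2$data)
  e3 <- synth_eeg(pr, n_channels = 3, duration = 2, fs = 250, seed = 6)
  expect_false(identical(e1$data, e3$data))
})

band_power <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 11,
                          plot = FALSE, detrend = TRUE)
  sum(sp$spec[sp$freq >= lo & sp$freq < hi])
}

test_that("AD-like profile has dominant slow-band power", {
  e <- synth_eeg(synth_profile("ad", seed = 3), n_channels = 2,
                 duration = 30, fs = 250)
  for (ch in 1:2) {
    slow <- band_power(e$data[ch, ], 250, 0.5, 8)
    alpha <- band_power(e$data[ch, ], 250, 8, 13)
    expect_gt(slow / alpha, 1)
  }
})

test_that("NC-like profile peaks near its alpha centre", {
  e <- synth_eeg(synth_profile("nc", seed = 4, alpha_peak_hz = 10),
                 n_channels = 2, duration = 30, fs = 250)
  for (ch in 1:2) {
    sp <- stats::spec.pgram(stats::ts(e$data[ch, ], frequency = 250),
                            spans = 11, plot = FALSE, detrend = TRUE)
    fmax <- sp$freq[which.max(sp$spec)]
    expect_gt(fmax, 8)
    expect_lt(fmax, 12)
  }
})

test_that("spectral ordering follows the profile for strong weight ratios", {
  # band-weight ratio 4 between theta and beta must show up as a
  # periodogram power ordering in the same direction
  pr <- synth_profile(band_powers = c(delta = 0.1, theta = 0.4, alpha = 0.1,
                                      beta = 0.1, gamma = 0.1),
                      noise_floor = 0.05, seed = 9)
  e <- synth_eeg(pr, n_channels = 1, duration = 30, fs = 250)
  expect_gt(band_power(e$data[1, ], 250, 4, 8),
            band_power(e$data[1, ], 250, 13, 30))
})

test_that("synthetic EEG amplitudes sit in the physiological range", {
  e <- synth_eeg(synth_profile("nc", seed = 1), n_channels = 4,
                 duration = 5, fs = 250, target_sd = 20)
  expect_equal(stats::sd(as.vector(e$data)), 20, tolerance = 1e-9)
})

test_that("invalid generator arguments are rejected", {
  pr <- synth_profile("nc")
  expect_error(synth_eeg(pr, duration = 0), "positive")
  expect_error(synth_eeg(pr, duration = 1, fs = -5), "positive")
  expect_error(synth_eeg(synth_profile("nc", alpha_peak_hz = 300),
                         duration = 1, fs = 250), "fs/2")
  expect_error(synth_profile(band_powers = c(delta = -1, theta = 1, alpha = 1,
                                             beta = 1, gamma = 1)),
               "nonnegative")
})
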