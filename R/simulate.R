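# Software stand-in for the physical rig: a speaker drives the fundamental
# (0,1) mode of the mirror-bearing membrane; mirror tilt deflects the laser
# onto the screen; a camera-style integrator renders the moving spot into
# 8-bit frames.

#' Simulate the laser-spot trajectory on the screen
#'
#' The fundamental-mode displacement `u(t)` follows a driven damped harmonic
#' oscillator `u'' + (w01/Q) u' + w01^2 u = kappa p(t)` with `w01 = 2 pi f01`
#' and `p(t)` the audio samples, discretized by the bilinear transform into a
#' biquad filter (exact to the warping error, negligible for f01 far below
#' the audio rate). Mirror tilt is proportional to modal displacement,
#' `theta(t) = gain * u(t)`; the second deflection axis is driven by a
#' delayed copy of `u` so that narrowband drive draws Lissajous-like closed
#' figures instead of a line (set `axis_delay = 0` for a single-axis rig).
#' The default delay, 25 ms, is a quarter period of a 10 Hz alpha rhythm:
#' the band the apparatus is meant to make visible then draws open loops
#' while slower drift still draws thin strokes. Scale it by `1/time_scale`
#' when the sonification compresses time.
#' A tilt `theta` deflects the reflected beam by `2 theta`, so the spot
#' moves by `mirror_to_screen * tan(2 theta)` along each axis; the
#' horizontal axis is stretched by `1 / cos(incidence_angle)` because the
#' assembly faces the screen obliquely. Excursions beyond the screen are
#' clamped and flagged.
#'
#' @param audio An [audio_waveform()] (normalized drive signal).
#' @param spec A [membrane_spec()].
#' @param geom An [optical_geometry()].
#' @param gain Mirror tilt per unit modal displacement, rad.
#' @param kappa Drive coupling; the default `(2 pi f01)^2` gives unit
#'   quasi-static response (`u ~ p` for drive far below resonance).
#' @param axis_delay Delay (s) of the copy of `u` driving the vertical axis.
#' @return A tibble of class `spot_trajectory` with columns `t` (s), `u`
#'   (modal displacement, drive units), `x`, `y` (screen metres, origin at
#'   screen centre), `clipped`; attributes `fs` and `geometry`.
#' @export
simulate_spot_trajectory <- function(audio, spec, geom = optical_geometry(),
                                     gain = 0.15, kappa = NULL,
                                     axis_delay = 0.025) {
  stopifnot(inherits(audio, "audio_waveform"), inherits(spec, "membrane_spec"),
            inherits(geom, "optical_geometry"))
  p <- audio$samples
  if (length(p) == 0) stop("zero-length audio", call. = FALSE)
  fs <- audio$fs_audio
  w0 <- 2 * pi * spec$f01
  if (is.null(kappa)) kappa <- w0^2
  Q <- spec$q_factor

  # bilinear-transform biquad for H(s) = kappa / (s^2 + (w0/Q) s + w0^2),
  # prewarped so the digital resonance sits exactly at f01
  K <- 2 * fs
  w0w <- K * tan(w0 / K)
  d0 <- K^2 + (w0w / Q) * K + w0w^2
  b <- kappa * c(1, 2, 1) / d0
  a <- c(1, (2 * w0w^2 - 2 * K^2) / d0, (K^2 - (w0w / Q) * K + w0w^2) / d0)
  u <- as.numeric(signal::filter(b, a, p))

  dlag <- round(axis_delay * fs)
  u2 <- if (dlag > 0 && dlag < length(u)) {
    c(rep(0, dlag), u[seq_len(length(u) - dlag)])
  } else u

  # clamp tilt so tan(2 theta) stays on its principal branch
  theta_max <- 0.7
  thx <- pmin(pmax(gain * u, -theta_max), theta_max)
  thy <- pmin(pmax(gain * u2, -theta_max), theta_max)
  L <- geom$mirror_to_screen
  x <- geom$rest_spot[1] + L * tan(2 * thx) / cos(geom$incidence_angle * pi / 180)
  y <- geom$rest_spot[2] + L * tan(2 * thy)

  hx <- geom$screen_width / 2
  hy <- geom$screen_height / 2
  clipped <- abs(x) > hx | abs(y) > hy
  x <- pmin(pmax(x, -hx), hx)
  y <- pmin(pmax(y, -hy), hy)

  out <- tibble::tibble(t = (seq_along(p) - 1) / fs, u = u,
                        x = x, y = y, clipped = clipped)
  class(out) <- c("spot_trajectory", class(out))
  attr(out, "fs") <- fs
  attr(out, "geometry") <- geom
  out
}

#' Render a spot trajectory into camera-style frames
#'
#' Each frame integrates a Gaussian point-spread spot along the trajectory
#' segment falling inside its exposure window: trajectory samples are binned
#' into a pixel histogram, blurred with a separable Gaussian of standard
#' deviation `psf_sigma` pixels, converted to 8-bit intensity (fixed-gain
#' sensor model by default, see `normalize`), offset by the sensor black
#' level, then additive Gaussian sensor noise is applied, rounded and
#' clamped to [0, 255]. Deterministic given `seed`.
#'
#' @param traj A [simulate_spot_trajectory()] result.
#' @param fps Frame rate, frames per second.
#' @param resolution Frame size `c(width, height)` in pixels.
#' @param psf_sigma Point-spread standard deviation in pixels.
#' @param exposure Exposure window per frame, seconds; defaults to `1/fps`
#'   (full-frame integration, motion-blurring the trace).
#' @param noise_sigma Sensor noise standard deviation, 8-bit intensity units.
#' @param seed RNG seed for the sensor noise.
#' @param normalize `"fixed"` (default) models a fixed-gain sensor: pixel
#'   intensity is proportional to the spot's dwell density, saturating at
#'   255 once a pixel collects `sat_dwell` of the exposure window -- so a
#'   fast-moving spot leaves a long dim trace and a slow spot a short
#'   bright one, as a real camera records. `"frame"` rescales every frame
#'   so its maximum is 255 (auto-gain).
#' @param sat_dwell Fraction of the exposure window dwelt in one pixel
#'   (after PSF spreading) that saturates the sensor, for
#'   `normalize = "fixed"`.
#' @param black_level Sensor pedestal added to every pixel (8-bit units).
#'   A nonzero pedestal keeps the dark background above the clamp at 0, so
#'   additive noise stays symmetric there, as in real camera output.
#' @return A [frame_sequence()].
#' @export
render_frames <- function(traj, fps = 10, resolution = c(120, 90),
                          psf_sigma = 2, exposure = 1 / fps,
                          noise_sigma = 0, seed = 1L,
                          normalize = c("fixed", "frame"),
                          sat_dwell = 0.002, black_level = 12) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(traj, "spot_trajectory"))
  if (fps <= 0) stop("`fps` must be > 0", call. = FALSE)
  if (exposure > 1 / fps + 1e-12) {
    stop("`exposure` cannot exceed the frame interval 1/fps", call. = FALSE)
  }
  geom <- attr(traj, "geometry")
  fs <- attr(traj, "fs")
  wpx <- as.integer(resolution[1])
  hpx <- as.integer(resolution[2])
  n <- nrow(traj)
  n_frames <- floor(n / fs * fps)
  if (n_frames < 1) stop("trajectory shorter than one frame", call. = FALSE)

  # screen metres -> pixel indices (row 1 = top of screen)
  col_idx <- pmin(pmax(ceiling((traj$x + geom$screen_width / 2) /
                                 geom$screen_width * wpx), 1L), wpx)
  row_idx <- pmin(pmax(ceiling((geom$screen_height / 2 - traj$y) /
                                 geom$screen_height * hpx), 1L), hpx)
  cell <- row_idx + (col_idx - 1L) * hpx

  i <- seq_len(hpx)
  j <- seq_len(wpx)
  Kh <- exp(-outer(i, i, `-`)^2 / (2 * psf_sigma^2))
  Kw <- exp(-outer(j, j, `-`)^2 / (2 * psf_sigma^2))

  spf <- fs / fps # samples per frame interval
  nexp <- max(1, floor(exposure * fs))
  frames <- withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      start <- floor((f - 1) * spf) + 1
      idx <- start:min(start + nexp - 1, n)
      counts <- tabulate(cell[idx], nbins = hpx * wpx)
      M <- matrix(counts / length(idx), nrow = hpx, ncol = wpx)
      B <- Kh %*% M %*% Kw
      if (normalize == "fixed") {
        B <- pmin(B / sat_dwell, 1) * 255
      } else {
        mx <- max(B)
        if (mx > 0) B <- B * (255 / mx)
      }
      B <- B + black_level
      if (noise_sigma > 0) {
        B <- B + stats::rnorm(length(B), sd = noise_sigma)
      }
      matrix(as.integer(pmin(pmax(round(B), 0), 255)), nrow = hpx, ncol = wpx)
    })
  })
  frame_sequence(frames, fps = fps, t0 = traj$t[1],
                 source_id = "simulated")
}
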