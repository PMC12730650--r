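#' Frame sequence container
#'
#' An ordered list of 8-bit grayscale rasters (integer matrices, 0-255,
#' row 1 = top) with a frame rate and start time.
#'
#' @param frames List of numeric/integer matrices, all the same size.
#' @param fps Frames per second (> 0).
#' @param t0 Timestamp of the first frame, seconds.
#' @param source_id Provenance string.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps, t0 = 0, source_id = "") {
  if (!is.list(frames) || length(frames) == 0) {
    stop("`frames` must be a nonempty list of matrices", call. = FALSE)
  }
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1) stop("all frames must share one size", call. = FALSE)
  if (fps <= 0) stop("`fps` must be > 0", call. = FALSE)
  structure(
    list(frames = frames, fps = fps, t0 = t0, source_id = source_id),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames of %dx%d px @ %g fps (%.1f s)\n",
              length(x$frames), d[1], d[2], x$fps, length(x$frames) / x$fps))
  invisible(x)
}

#' Frame timestamps
#' @param seq A [frame_sequence()].
#' @return Numeric vector of per-frame start times in seconds.
#' @export
frame_times <- function(seq) {
  seq$t0 + (seq_along(seq$frames) - 1) / seq$fps
}

#' Extract a fixed analysis window from a frame sequence
#'
#' Standardises recordings to a common analysis window (275 s in the
#' reference protocol), dropping initial settling artifacts via
#' `start_offset` and anything after `start_offset + duration`.
#'
#' @param seq A [frame_sequence()].
#' @param start_offset Seconds to skip from the start (>= 0).
#' @param duration Window length in seconds (default 275).
#' @return A [frame_sequence()] of exactly `round(duration * fps)` frames
#'   starting at the first frame with `t >= t0 + start_offset`.
#' @export
trim_window <- function(seq, start_offset = 0, duration = 275) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (start_offset < 0) stop("`start_offset` must be >= 0", call. = FALSE)
  t <- frame_times(seq)
  first <- which(t >= seq$t0 + start_offset - 1e-9)[1]
  n_keep <- round(duration * seq$fps)
  if (is.na(first) || first + n_keep - 1 > length(seq$frames)) {
    stop(sprintf(
      "window [%g, %g] s exceeds the %.1f s sequence",
      start_offset, start_offset + duration, length(seq$frames) / seq$fps),
      call. = FALSE)
  }
  frame_sequence(seq$frames[first:(first + n_keep - 1)], fps = seq$fps,
                 t0 = t[first], source_id = seq$source_id)
}

#' Read / write a directory of grayscale PNG frames
#'
#' Frames are read in lexicographic filename order and converted to 8-bit
#' grayscale with the Rec. 601 luma (0.299 R + 0.587 G + 0.114 B) when the
#' PNG has colour channels.
#'
#' @param path Directory of `.png` files.
#' @param fps Frame rate to stamp on the sequence.
#' @param t0,source_id Passed to [frame_sequence()].
#' @return A [frame_sequence()].
#' @export
read_frames_dir <- function(path, fps = 10, t0 = 0, source_id = path) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no .png frames in ", path, call. = FALSE)
  frames <- lapply(files, function(f) {
    a <- png::readPNG(f)
    g <- if (length(dim(a)) == 3) {
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else a
    matrix(as.integer(round(g * 255)), nrow = nrow(g))
  })
  frame_sequence(frames, fps = fps, t0 = t0, source_id = source_id)
}

#' @rdname read_frames_dir
#' @param seq A [frame_sequence()] to write.
#' @param prefix Filename prefix.
#' @export
write_frames_dir <- function(seq, path, prefix = "frame") {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(seq$frames)) {
    png::writePNG(seq$frames[[i]] / 255,
                  file.path(path, sprintf("%s_%05d.png", prefix, i)))
  }
  invisible(path)
}

#' Adaptive (local-mean) thresholding
#'
#' Binarizes a grayscale frame against the locally adapted threshold
#' `T(x, y) = mu(x, y) - C`, where `mu` is the mean intensity within a
#' `window x window` neighbourhood centred on the pixel -- uniform for
#' `weighting = "mean"` (Bradley-Roth style), Gaussian-weighted for
#' `weighting = "gaussian"`. A pixel becomes foreground (255) iff its value
#' is strictly greater than the threshold; borders use replicate padding.
#'
#' @param frame Numeric/integer matrix (8-bit grayscale).
#' @param window Odd neighbourhood side length in px, >= 3 (default 31).
#' @param C Constant offset subtracted from the local mean (default 2).
#' @param weighting `"gaussian"` or `"mean"`.
#' @return Integer matrix over {0, 255}.
#' @export
adaptive_threshold <- function(frame, window = 31, C = 2,
                               weighting = c("gaussian", "mean")) {
  weighting <- match.arg(weighting)
  frame <- as.matrix(frame)
  if (window %% 2 == 0 || window < 3) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  r <- (window - 1) %/% 2
  P <- pad_replicate(frame, r)
  mu <- if (weighting == "mean") {
    box_mean(P, window)
  } else {
    # OpenCV's Gaussian kernel width rule for adaptive thresholding
    sigma <- 0.3 * ((window - 1) * 0.5 - 1) + 0.8
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    k <- k / sum(k)
    sep_filter_valid(P, k)
  }
  out <- ifelse(frame > mu - C, 255L, 0L)
  matrix(as.integer(out), nrow = nrow(frame))
}

pad_replicate <- function(m, r) {
  if (r == 0) return(m)
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# mean over a w x w box for every "valid" position of padded matrix P,
# via a summed-area table
box_mean <- function(P, w) {
  S <- apply(P, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  S <- rbind(0, cbind(0, S))
  h <- nrow(P) - w + 1
  wd <- ncol(P) - w + 1
  i2 <- (w + 1):(w + h); i1 <- 1:h
  j2 <- (w + 1):(w + wd); j1 <- 1:wd
  (S[i2, j2] - S[i1, j2] - S[i2, j1] + S[i1, j1]) / (w * w)
}

# separable "valid" correlation of padded matrix P with 1-D kernel k
sep_filter_valid <- function(P, k) {
  w <- length(k)
  h <- nrow(P) - w + 1
  A <- matrix(0, h, nrow(P))
  for (o in seq_len(w)) A[cbind(seq_len(h), seq_len(h) + o - 1)] <- k[o]
  wd <- ncol(P) - w + 1
  Bt <- matrix(0, ncol(P), wd)
  for (o in seq_len(w)) Bt[cbind(seq_len(wd) + o - 1, seq_len(wd))] <- k[o]
  A %*% P %*% Bt
}

#' 3x3 elliptical structuring element
#'
#' The 3x3 discrete ellipse (a cross: the centre plus its 4-neighbours),
#' matching the conventional elliptical element of that size.
#'
#' @return 0/1 integer matrix.
#' @export
selem_ellipse3 <- function() {
  matrix(c(0L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L), nrow = 3)
}

shift_pad <- function(m, di, dj, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_i <- seq_len(h) + di
  src_j <- seq_len(w) + dj
  ok_i <- src_i >= 1 & src_i <= h
  ok_j <- src_j >= 1 & src_j <= w
  out[which(ok_i), which(ok_j)] <- m[src_i[ok_i], src_j[ok_j], drop = FALSE]
  out
}

binary_erode <- function(fg, selem) {
  offs <- which(selem == 1, arr.ind = TRUE)
  ctr <- (dim(selem) + 1) / 2
  out <- matrix(TRUE, nrow(fg), ncol(fg))
  for (k in seq_len(nrow(offs))) {
    # outside-image treated as foreground: border-touching regions survive
    out <- out & shift_pad(fg, offs[k, 1] - ctr[1], offs[k, 2] - ctr[2], TRUE)
  }
  out
}

binary_dilate <- function(fg, selem) {
  offs <- which(selem == 1, arr.ind = TRUE)
  ctr <- (dim(selem) + 1) / 2
  out <- matrix(FALSE, nrow(fg), ncol(fg))
  for (k in seq_len(nrow(offs))) {
    # reflected element; outside-image contributes background
    out <- out | shift_pad(fg, ctr[1] - offs[k, 1], ctr[2] - offs[k, 2], FALSE)
  }
  out
}

#' Morphological opening of a binary frame
#'
#' Erosion followed by dilation with the same structuring element (default
#' the 3x3 ellipse/cross), removing isolated specks smaller than the element
#' while preserving larger structures. Pixels outside the image count as
#' foreground for the erosion and background for the dilation, so solid
#' regions touching the border survive.
#'
#' @param b Binary matrix over {0, 255} (any nonzero value is foreground).
#' @param selem 0/1 structuring element with odd dimensions.
#' @return Integer matrix over {0, 255}.
#' @export
morphological_opening <- function(b, selem = selem_ellipse3()) {
  b <- as.matrix(b)
  fg <- b != 0
  opened <- binary_dilate(binary_erode(fg, selem), selem)
  matrix(ifelse(opened, 255L, 0L), nrow = nrow(b))
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass over the label adjacency.
label_components8 <- function(fg) {
  lab <- EBImage::bwlabel(matrix(as.numeric(fg), nrow = nrow(fg)))
  lab <- matrix(as.integer(lab), nrow = nrow(fg))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  h <- nrow(lab); w <- ncol(lab)
  for (sh in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(h - 1), if (sh[2] == 1) seq_len(w - 1) else 2:w]
    b <- lab[2:h, if (sh[2] == 1) 2:w else seq_len(w - 1)]
    pairs <- unique(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]))
    if (length(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' Contour-envelope masking of a binary frame
#'
#' Isolates the primary projected structure. The binary frame is inverted;
#' holes of the inverted foreground (background regions with no
#' 4-connected path to the image border) are closed; the largest
#' 8-connected structure of the hole-closed image -- the filled outline of
#' the primary vibrational pattern -- becomes a boolean mask (ties broken
#' by first occurrence in column-major scan order). Output pixels are the
#' input values inside the mask and 0 elsewhere.
#'
#' @param b Binary matrix over {0, 255}.
#' @return An object of class `masked_frame`: list with `pixels` (masked
#'   {0,255} matrix), `mask` (logical matrix), `valid` (FALSE when the frame
#'   is degenerate: no foreground at all, or nothing to contour after
#'   inversion).
#' @export
envelope_mask <- function(b) {
  b <- as.matrix(b)
  h <- nrow(b); w <- ncol(b)
  empty <- function() {
    structure(list(pixels = matrix(0L, h, w),
                   mask = matrix(FALSE, h, w), valid = FALSE),
              class = "masked_frame")
  }
  fg <- b != 0
  if (!any(fg)) return(empty())
  inv <- !fg
  if (!any(inv)) return(empty())
  # close holes: background (= !inv) regions not reaching the border
  bg4 <- matrix(as.integer(EBImage::bwlabel(matrix(as.numeric(!inv), h, w))),
                nrow = h)
  border_labs <- unique(c(bg4[1, ], bg4[h, ], bg4[, 1], bg4[, w]))
  filled <- inv | (bg4 > 0 & !(bg4 %in% border_labs))
  lab <- label_components8(filled)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  sel <- which.max(areas) # ties: lowest label = first-found in scan order
  mask <- lab == sel
  out <- b
  out[!mask] <- 0L
  structure(list(pixels = matrix(as.integer(out), nrow = h),
                 mask = mask, valid = TRUE),
            class = "masked_frame")
}

#' Additive Gaussian intensity noise
#'
#' Robustness perturbation: per-pixel additive `N(0, sigma^2)` on the 8-bit
#' intensity scale, rounded and clamped to [0, 255]. Deterministic given
#' `seed`.
#'
#' @param frame Grayscale matrix (0-255).
#' @param sigma Noise standard deviation in intensity units (default 5).
#' @param seed RNG seed.
#' @return Integer matrix over [0, 255].
#' @export
inject_noise <- function(frame, sigma = 5, seed = 1L) {
  frame <- as.matrix(frame)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) {
    return(matrix(as.integer(round(frame)), nrow = nrow(frame)))
  }
  noisy <- withr::with_seed(seed, frame + stats::rnorm(length(frame), sd = sigma))
  matrix(as.integer(pmin(pmax(round(noisy), 0), 255)), nrow = nrow(frame))
}

#' Run the full frame-processing chain over a sequence
#'
#' Optional trimming, optional Gaussian noise injection (applied to the
#' grayscale frames, before binarization), adaptive thresholding,
#' morphological opening, and contour-envelope masking.
#'
#' @param seq A [frame_sequence()].
#' @param window,C,weighting Passed to [adaptive_threshold()].
#' @param selem Passed to [morphological_opening()].
#' @param noise_sigma Injection noise SD; 0 disables.
#' @param seed Base seed for noise injection (one derived seed per frame).
#' @param start_offset,duration If `duration` is non-`NULL`, the sequence is
#'   first passed through [trim_window()].
#' @param mask_source Which binary frame the envelope contour is computed
#'   on. `"binarized"` (default) contours the inverted thresholded frame
#'   before opening: the dark halo outlining the trace is the dominant dark
#'   structure there, so the filled largest contour isolates the primary
#'   trajectory. `"cleaned"` contours the inverted opened frame; at
#'   speckle-heavy noise levels the opening turns most of the background
#'   dark, and the largest inverted component becomes the background rather
#'   than the trace envelope. The mask is always applied to the cleaned
#'   frame.
#' @return An object of class `masked_sequence`: list with `frames` (list of
#'   [envelope_mask()] results), `fps`, `t` (timestamps), `source_id`, and
#'   the processing `params`.
#' @export
process_frames <- function(seq, window = 31, C = 2,
                           weighting = c("gaussian", "mean"),
                           selem = selem_ellipse3(),
                           noise_sigma = 0, seed = 1L,
                           start_offset = 0, duration = NULL,
                           mask_source = c("binarized", "cleaned")) {
  weighting <- match.arg(weighting)
  mask_source <- match.arg(mask_source)
  stopifnot(inherits(seq, "frame_sequence"))
  if (!is.null(duration)) {
    seq <- trim_window(seq, start_offset = start_offset, duration = duration)
  }
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                             length(seq$frames)))
  masked <- lapply(seq_along(seq$frames), function(i) {
    f <- seq$frames[[i]]
    if (noise_sigma > 0) f <- inject_noise(f, sigma = noise_sigma, seed = seeds[i])
    bin <- adaptive_threshold(f, window = window, C = C, weighting = weighting)
    cln <- morphological_opening(bin, selem)
    if (mask_source == "cleaned") {
      envelope_mask(cln)
    } else {
      mf <- envelope_mask(bin)
      out <- cln
      out[!mf$mask] <- 0L
      mf$pixels <- matrix(as.integer(out), nrow = nrow(cln))
      mf
    }
  })
  structure(
    list(frames = masked, fps = seq$fps, t = frame_times(seq),
         source_id = seq$source_id,
         params = list(window = window, C = C, weighting = weighting,
                       noise_sigma = noise_sigma, seed = seed,
                       start_offset = start_offset, duration = duration,
                       mask_source = mask_source)),
    class = "masked_sequence"
  )
}
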