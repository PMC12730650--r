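# Per-frame spatial descriptors of the masked binary patterns, and the
# across-frame centroid-trajectory dynamics.

as_pixel_matrix <- function(f) {
  if (inherits(f, "masked_frame")) f$pixels else as.matrix(f)
}

#' Active area of a masked frame
#'
#' Number of white pixels (intensity 255) within the envelope mask; the
#' spatial extent of the vibrational pattern at one instant.
#'
#' @param f A `masked_frame` or binary matrix over {0, 255}.
#' @return Integer pixel count.
#' @export
active_area <- function(f) {
  sum(as_pixel_matrix(f) == 255)
}

#' Shannon spatial entropy of a binary frame
#'
#' `H = -sum_k p(k) log2 p(k)` over the pixel-intensity distribution, which
#' for a binary frame reduces to the binary entropy of the white-pixel
#' fraction; at most 1 bit, 0 for a uniform frame (`0 log 0 := 0`).
#'
#' @param f A `masked_frame` or binary matrix.
#' @return Entropy in bits.
#' @export
spatial_entropy <- function(f) {
  m <- as_pixel_matrix(f)
  if (length(m) == 0) stop("empty frame", call. = FALSE)
  p <- mean(m == 255)
  binary_entropy(p)
}

binary_entropy <- function(p) {
  h <- 0
  if (p > 0) h <- h - p * log2(p)
  if (p < 1) h <- h - (1 - p) * log2(1 - p)
  h
}

#' Box-counting fractal dimension of a binary pattern
#'
#' The frame is overlaid with grids of square cells of decreasing side
#' `epsilon` (anchored at the top-left corner); `N(epsilon)` counts cells
#' containing at least one foreground pixel, and the dimension is the
#' least-squares slope of `log N(epsilon)` against `log(1/epsilon)` over all
#' box sizes, clamped to [0, 2]. Default box sides are the powers of two
#' from `min(nrow, ncol)/2` down to 2.
#'
#' @param f A `masked_frame` or binary matrix.
#' @param box_sizes Decreasing vector of >= 2 cell sides in px, or `NULL`
#'   for the default dyadic ladder.
#' @return Estimated dimension, or `NA` for an all-background frame
#'   (flagged, not an error).
#' @export
fractal_dimension <- function(f, box_sizes = NULL) {
  m <- as_pixel_matrix(f)
  if (length(m) == 0) stop("empty frame", call. = FALSE)
  if (is.null(box_sizes)) {
    emax <- 2^floor(log2(min(dim(m)) / 2))
    if (emax < 2) stop("frame too small for box counting", call. = FALSE)
    box_sizes <- 2^(floor(log2(emax)):1)
  }
  if (length(box_sizes) < 2) stop("need at least 2 box sizes", call. = FALSE)
  fgidx <- which(m != 0, arr.ind = TRUE)
  if (nrow(fgidx) == 0) return(NA_real_)
  n_cells <- vapply(box_sizes, function(e) {
    ci <- (fgidx[, 1] - 1L) %/% e
    cj <- (fgidx[, 2] - 1L) %/% e
    length(unique(ci + cj * (1L + max(ci))))
  }, numeric(1))
  lx <- log(1 / box_sizes)
  ly <- log(n_cells)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  min(max(slope, 0), 2)
}

#' Centroid of the white pixels
#'
#' Arithmetic mean of the white-pixel coordinates, in 0-based pixel
#' coordinates with x = column and y = row, origin at the top-left.
#'
#' @param f A `masked_frame` or binary matrix.
#' @return Named numeric `c(x, y)`, or `c(NA, NA)` for a frame with no
#'   white pixels (flagged invalid downstream).
#' @export
centroid <- function(f) {
  m <- as_pixel_matrix(f)
  idx <- which(m == 255, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(x = NA_real_, y = NA_real_))
  c(x = mean(idx[, 2] - 1), y = mean(idx[, 1] - 1))
}

#' Per-frame descriptor table
#'
#' Computes all spatial descriptors for every frame of a processed
#' (masked) sequence.
#'
#' @param mseq A `masked_sequence` from [process_frames()].
#' @param box_sizes Passed to [fractal_dimension()].
#' @return A tibble with one row per frame: `frame_index`, `time_s`,
#'   `active_area`, `entropy`, `fractal_dim`, `centroid_x`, `centroid_y`,
#'   `valid`. `valid` is `FALSE` when no primary contour was found or no
#'   white pixel survived masking.
#' @export
frame_descriptors <- function(mseq, box_sizes = NULL) {
  stopifnot(inherits(mseq, "masked_sequence"))
  rows <- purrr::map2(mseq$frames, seq_along(mseq$frames), function(mf, i) {
    aa <- active_area(mf)
    ok <- isTRUE(mf$valid) && aa > 0
    cen <- centroid(mf)
    tibble::tibble(
      frame_index = i,
      time_s = mseq$t[i],
      active_area = aa,
      entropy = spatial_entropy(mf),
      fractal_dim = if (ok) fractal_dimension(mf, box_sizes) else NA_real_,
      centroid_x = cen[["x"]],
      centroid_y = cen[["y"]],
      valid = ok
    )
  })
  dplyr::bind_rows(rows)
}

#' Centroid-trajectory dynamics
#'
#' Reconstructs the temporal trajectory of the pattern's centre of mass and
#' its displacement dynamics: per-step Euclidean displacements between
#' consecutive valid frames and the accumulated (prefix-sum) displacement.
#' Invalid frames are skipped; their indices are recorded.
#'
#' @param desc A [frame_descriptors()] tibble.
#' @return An object of class `trajectory_metrics`: list with `path`
#'   (tibble `frame_index`, `time_s`, `x`, `y`), `step_displacements`
#'   (length `nrow(path) - 1`), `cumulative_displacement` (same length,
#'   nondecreasing), and `skipped_frames`.
#' @export
trajectory_metrics <- function(desc) {
  stopifnot(is.data.frame(desc))
  ok <- desc$valid
  if (!any(ok)) stop("no valid frames: empty trajectory", call. = FALSE)
  path <- tibble::tibble(
    frame_index = desc$frame_index[ok],
    time_s = desc$time_s[ok],
    x = desc$centroid_x[ok],
    y = desc$centroid_y[ok]
  )
  steps <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  structure(
    list(path = path,
         step_displacements = steps,
         cumulative_displacement = cumsum(steps),
         skipped_frames = desc$frame_index[!ok]),
    class = "trajectory_metrics"
  )
}

#' Per-frame feature table for classification
#'
#' Assembles the classifier's input: the per-frame feature vector
#' `[active_area, entropy, fractal_dim, centroid_x, centroid_y, step_disp]`
#' (`step_disp` is the centroid displacement from the previous valid frame,
#' 0 for the first), with the group label and source identity attached.
#'
#' @param mseq A `masked_sequence` from [process_frames()].
#' @param group_label `"Control"` or `"Alzheimer"` (or any label).
#' @param source_id Identifier of the originating recording/video.
#' @param box_sizes Passed to [fractal_dimension()].
#' @return A tibble, invalid frames dropped, columns `frame_index`,
#'   `time_s`, `group_label`, `source_id`, the six features, `valid`.
#' @export
features_from_frames <- function(mseq, group_label, source_id = mseq$source_id,
                                 box_sizes = NULL) {
  desc <- frame_descriptors(mseq, box_sizes)
  desc <- dplyr::filter(desc, .data$valid)
  if (nrow(desc) == 0) {
    stop("no valid frames to build features from", call. = FALSE)
  }
  step <- c(0, sqrt(diff(desc$centroid_x)^2 + diff(desc$centroid_y)^2))
  dplyr::mutate(desc,
                step_disp = step,
                group_label = group_label,
                source_id = source_id,
                .after = "time_s")
}

#' Feature column names used by the classifier
#' @return Character vector of the six per-frame feature columns.
#' @export
feature_columns <- function() {
  c("active_area", "entropy", "fractal_dim", "centroid_x", "centroid_y",
    "step_disp")
}
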