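# Brute-force oracles, written directly from the set-theoretic / per-pixel
# definitions of each operation. Deliberately slow and independent of the
# package's vectorised implementations.

# local mean threshold: per-pixel double loop, replicate padding, uniform
# window, strict '>' against mean - C
oracle_adaptive_mean <- function(frame, window, C) {
  r <- (window - 1) %/% 2
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- min(max(i + di, 1), h)
          jj <- min(max(j + dj, 1), w)
          acc <- acc + frame[ii, jj]
        }
      }
      mu <- acc / (window * window)
      out[i, j] <- if (frame[i, j] > mu - C) 255L else 0L
    }
  }
  out
}

# erosion: output fg iff all element-covered positions are fg; positions
# outside the image count as foreground
oracle_erode <- function(fg, selem) {
  h <- nrow(fg); w <- ncol(fg)
  ctr <- (dim(selem) + 1) / 2
  offs <- which(selem == 1, arr.ind = TRUE)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      keep <- TRUE
      for (k in seq_len(nrow(offs))) {
        ii <- i + offs[k, 1] - ctr[1]
        jj <- j + offs[k, 2] - ctr[2]
        inside <- ii >= 1 && ii <= h && jj >= 1 && jj <= w
        if (inside && !fg[ii, jj]) { keep <- FALSE; break }
      }
      out[i, j] <- keep
    }
  }
  out
}

# dilation with the reflected element; outside-image contributes background
oracle_dilate <- function(fg, selem) {
  h <- nrow(fg); w <- ncol(fg)
  ctr <- (dim(selem) + 1) / 2
  offs <- which(selem == 1, arr.ind = TRUE)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      hit <- FALSE
      for (k in seq_len(nrow(offs))) {
        ii <- i - (offs[k, 1] - ctr[1])
        jj <- j - (offs[k, 2] - ctr[2])
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && fg[ii, jj]) {
          hit <- TRUE; break
        }
      }
      out[i, j] <- hit
    }
  }
  out
}

oracle_opening <- function(b, selem) {
  fg <- b != 0
  opened <- oracle_dilate(oracle_erode(fg, selem), selem)
  matrix(ifelse(opened, 255L, 0L), nrow = nrow(b))
}

# 8-connected component labelling by BFS flood fill
oracle_components8 <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j0 in seq_len(w)) {
    for (i0 in seq_len(h)) {
      if (!fg[i0, j0] || lab[i0, j0] > 0) next
      cur <- cur + 1L
      queue <- list(c(i0, j0))
      lab[i0, j0] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
              fg[ii, jj] && lab[ii, jj] == 0) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# fill holes of a single component: background cells (4-connected) not
# reachable from the border belong to the filled region
oracle_fill <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  outside <- matrix(FALSE, h, w)
  queue <- list()
  for (i in seq_len(h)) for (j in c(1, w)) {
    if (!mask[i, j] && !outside[i, j]) { outside[i, j] <- TRUE; queue[[length(queue) + 1]] <- c(i, j) }
  }
  for (j in seq_len(w)) for (i in c(1, h)) {
    if (!mask[i, j] && !outside[i, j]) { outside[i, j] <- TRUE; queue[[length(queue) + 1]] <- c(i, j) }
  }
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- p[1] + d[1]; jj <- p[2] + d[2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
          !mask[ii, jj] && !outside[ii, jj]) {
        outside[ii, jj] <- TRUE
        queue[[length(queue) + 1]] <- c(ii, jj)
      }
    }
  }
  mask | !outside
}

# full envelope-mask oracle: invert, close holes of the inverted foreground
# (background regions with no 4-path to the border), then the largest
# 8-connected structure of the hole-closed image (ties: first in
# column-major scan order) masks the input
oracle_envelope <- function(b) {
  h <- nrow(b); w <- ncol(b)
  fg <- b != 0
  if (!any(fg) || all(fg)) {
    return(list(pixels = matrix(0L, h, w), mask = matrix(FALSE, h, w),
                valid = FALSE))
  }
  inv <- !fg
  filled <- oracle_fill(inv)
  lab <- oracle_components8(filled)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  best <- which.max(areas)
  best_mask <- lab == best
  out <- b
  out[!best_mask] <- 0L
  list(pixels = matrix(as.integer(out), h, w), mask = best_mask, valid = TRUE)
}

# dyadic box counting by explicit grid scan
oracle_box_count <- function(m, e) {
  h <- nrow(m); w <- ncol(m)
  n <- 0L
  for (bi in seq(1, h, by = e)) {
    for (bj in seq(1, w, by = e)) {
      blk <- m[bi:min(bi + e - 1, h), bj:min(bj + e - 1, w), drop = FALSE]
      if (any(blk != 0)) n <- n + 1L
    }
  }
  n
}

# random binary/grayscale frame generators
random_binary_frame <- function(h, w, p = 0.5) {
  matrix(ifelse(stats::runif(h * w) < p, 255L, 0L), h, w)
}
random_gray_frame <- function(h, w) {
  matrix(as.integer(sample(0:255, h * w, replace = TRUE)), h, w)
}

# toy eeg_recording from a plain matrix
toy_eeg <- function(data, fs = 500, labels = NULL, group = "none") {
  eeg_recording(as.matrix(data), fs = fs, channel_labels = labels,
                group_label = group)
}

# hand-built spot_trajectory for rendering tests
manual_trajectory <- function(x, y, fs, geom = optical_geometry()) {
  out <- tibble::tibble(t = (seq_along(x) - 1) / fs, u = 0,
                        x = x, y = y, clipped = FALSE)
  class(out) <- c("spot_trajectory", class(out))
  attr(out, "fs") <- fs
  attr(out, "geometry") <- geom
  out
}

# binary entropy closed form for cross-checks
h2 <- function(p) {
  s <- 0
  if (p > 0) s <- s - p * log2(p)
  if (p < 1) s <- s - (1 - p) * log2(1 - p)
  s
}

desk_config <- function(seed, ad = "ad", nc = "nc", duration = 100) {
  pipeline_config(
    seed = seed,
    eeg = list(duration = duration, n_subjects = 3),
    profiles = list(ad = ad, nc = nc),
    sonify = list(fs_audio = 8000, time_scale = 1),
    render = list(width = 120L, height = 90L),
    frameproc = list(duration = NULL, trim_start_ad = 0, trim_start_nc = 0)
  )
}
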