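# Motion metrics: pyramidal iterated Lucas-Kanade optical flow, its spatial
# gradient, and set-level Freedman-Diaconis histograms.

# 2-D box sum with half-width r via integral images (edge handled by zero
# padding; the window is truncated at borders).
col_cumsum <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  v <- cumsum(m)
  out <- matrix(v, h, w)
  if (w > 1) out <- out - rep(c(0, v[h * seq_len(w - 1)]), each = h)
  out
}

box_sum <- function(m, r) {
  h <- nrow(m)
  w <- ncol(m)
  cs <- rbind(0, col_cumsum(m)) # (h+1) x w
  top <- pmax(0, seq_len(h) - r - 1)
  bot <- pmin(h, seq_len(h) + r)
  colsum <- cs[bot + 1, , drop = FALSE] - cs[top + 1, , drop = FALSE]
  cs2 <- t(rbind(0, col_cumsum(t(colsum))))
  left <- pmax(0, seq_len(w) - r - 1)
  right <- pmin(w, seq_len(w) + r)
  cs2[, right + 1, drop = FALSE] - cs2[, left + 1, drop = FALSE]
}

# Bilinear sampling of image `img` at (y + dy, x + dx); out-of-range samples
# clamp to the border.
bilinear_warp <- function(img, dy, dx) {
  h <- nrow(img)
  w <- ncol(img)
  yy <- matrix(seq_len(h), h, w) + dy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) + dx
  yy <- clamp(yy, 1, h)
  xx <- clamp(xx, 1, w)
  y0 <- pmin(floor(yy), h - 1)
  x0 <- pmin(floor(xx), w - 1)
  fy <- yy - y0
  fx <- xx - x0
  i00 <- y0 + (x0 - 1) * h
  img[i00] * (1 - fy) * (1 - fx) + img[i00 + 1] * fy * (1 - fx) +
    img[i00 + h] * (1 - fy) * fx + img[i00 + h + 1] * fy * fx
}

img_halve <- function(m) {
  (m[seq(1, nrow(m), 2), seq(1, ncol(m), 2)] +
     m[seq(2, nrow(m), 2), seq(1, ncol(m), 2)] +
     m[seq(1, nrow(m), 2), seq(2, ncol(m), 2)] +
     m[seq(2, nrow(m), 2), seq(2, ncol(m), 2)]) / 4
}

central_diff <- function(m, margin) {
  h <- nrow(m)
  w <- ncol(m)
  if (margin == 1) {
    rbind(m[2, ] - m[1, ],
          (m[3:h, , drop = FALSE] - m[1:(h - 2), , drop = FALSE]) / 2,
          m[h, ] - m[h - 1, ])
  } else {
    cbind(m[, 2] - m[, 1],
          (m[, 3:w, drop = FALSE] - m[, 1:(w - 2), drop = FALSE]) / 2,
          m[, w] - m[, w - 1])
  }
}

# Lucas-Kanade flow between two grayscale frames, coarse-to-fine with
# iterative warping. Returns u (x-flow) and v (y-flow) at full resolution.
lk_flow <- function(i1, i2, levels = 2L, iters = 2L, win = 2L, eps = 1e-4) {
  pyr1 <- list(i1)
  pyr2 <- list(i2)
  if (levels > 1) {
    for (l in 2:levels) {
      pyr1[[l]] <- img_halve(pyr1[[l - 1]])
      pyr2[[l]] <- img_halve(pyr2[[l - 1]])
    }
  }
  u <- v <- matrix(0, nrow(pyr1[[levels]]), ncol(pyr1[[levels]]))
  for (l in levels:1) {
    a <- pyr1[[l]]
    b <- pyr2[[l]]
    if (nrow(u) != nrow(a)) { # upsample flow
      u <- 2 * u[rep(seq_len(nrow(u)), each = 2), rep(seq_len(ncol(u)), each = 2)]
      v <- 2 * v[rep(seq_len(nrow(v)), each = 2), rep(seq_len(ncol(v)), each = 2)]
    }
    ix <- central_diff(a, 2)
    iy <- central_diff(a, 1)
    sxx <- box_sum(ix * ix, win)
    syy <- box_sum(iy * iy, win)
    sxy <- box_sum(ix * iy, win)
    det <- sxx * syy - sxy^2
    ok <- det > eps
    for (it in seq_len(iters)) {
      bw <- bilinear_warp(b, v, u)
      it_ <- bw - a
      sxt <- box_sum(ix * it_, win)
      syt <- box_sum(iy * it_, win)
      du <- clamp(ifelse(ok, -(syy * sxt - sxy * syt) / pmax(det, eps), 0), -2, 2)
      dv <- clamp(ifelse(ok, -(sxx * syt - sxy * sxt) / pmax(det, eps), 0), -2, 2)
      u <- u + du
      v <- v + dv
    }
  }
  list(u = u, v = v)
}

#' Optical-flow speed stack of a clip
#'
#' Iterated pyramidal Lucas-Kanade flow between the 19 consecutive frame
#' pairs of a 20-frame clip. The flow vector length (speed, px/frame) is
#' masked to the container interior and average-pooled to 32 x 32.
#'
#' @param clip a `movie_clip` (or any frames x h x w x 3 array).
#' @param mask logical h x w matrix (at clip resolution); speeds outside are
#'   zeroed.
#' @param levels,iters pyramid levels and warp iterations.
#' @return a 32 x 32 x 19 array of speeds (px/frame at clip resolution).
#' @export
optical_flow <- function(clip, mask = scene_mask(), levels = 2L, iters = 2L) {
  d <- dim(clip)
  if (is.na(d[1]) || d[1] < 2) stop("input error: clip needs at least 2 frames")
  g <- clip_gray(clip)
  n_pairs <- d[1] - 1
  # flow is estimated at the output (half) resolution after a light
  # pre-smoothing, which suppresses rendering-noise flows; speeds are
  # rescaled to full-resolution px/frame
  halves <- lapply(seq_len(d[1]), function(f) {
    m <- box_sum(box_sum(img_halve(g[f, , ]), 1), 1) / 81
    # global contrast standardisation: flow response should not depend on
    # the palette contrast of a particular rendering
    (m - mean(m)) / max(stats::sd(m), 1e-6) * 0.2
  })
  mh <- img_halve(mask * 1) > 0.5
  out <- array(0, c(d[2] / 2, d[3] / 2, n_pairs))
  for (f in seq_len(n_pairs)) {
    fl <- lk_flow(halves[[f]], halves[[f + 1]], levels, iters)
    sp <- 2 * sqrt(fl$u^2 + fl$v^2)
    sp[!mh] <- 0
    out[, , f] <- sp
  }
  out
}

#' Spatial gradient magnitude of a flow-speed stack
#'
#' Central-difference gradient in both directions of each temporal slice of
#' the optical-flow speed, combined as the gradient magnitude (a measure of
#' local accelerations/shear across space).
#'
#' @param flow a h x w x n_pairs speed array from [optical_flow()].
#' @return an array of the same shape.
#' @export
flow_gradient <- function(flow) {
  out <- array(0, dim(flow))
  for (f in seq_len(dim(flow)[3])) {
    gx <- central_diff(flow[, , f], 2)
    gy <- central_diff(flow[, , f], 1)
    out[, , f] <- sqrt(gx^2 + gy^2)
  }
  out
}

#' Freedman-Diaconis bin count for one sample
#' @param x numeric values.
#' @return a positive integer bin count.
#' @export
fd_bin_count <- function(x) {
  n <- length(x)
  iqr <- stats::IQR(x)
  if (iqr <= 0 || n < 2) return(1L)
  width <- 2 * iqr / n^(1 / 3)
  max(1L, as.integer(ceiling(diff(range(x)) / width)))
}

#' Shared histogram bins for a set of flow stacks
#'
#' The per-stimulus Freedman-Diaconis bin counts are averaged (and rounded)
#' across the whole stimulus set, and shared bin edges are laid over the
#' pooled value range, so that histograms are comparable between stimuli.
#'
#' @param flows list of flow (or flow-gradient) stacks.
#' @return list with `n_bins` and `edges` (length `n_bins + 1`).
#' @export
shared_flow_bins <- function(flows) {
  if (!length(flows)) stop("estimation error: empty flow set")
  counts <- vapply(flows, function(fl) fd_bin_count(as.numeric(fl)), integer(1))
  n_bins <- max(1L, as.integer(round(mean(counts))))
  rng <- range(vapply(flows, min, numeric(1)), vapply(flows, max, numeric(1)))
  if (diff(rng) == 0) rng <- rng + c(0, 1e-12)
  list(n_bins = n_bins, edges = seq(rng[1], rng[2], length.out = n_bins + 1))
}

#' Per-slice histogram of a flow stack under shared bins
#'
#' @param flow a h x w x n_pairs stack.
#' @param bins shared bins from [shared_flow_bins()].
#' @return an `n_bins x n_pairs` count matrix (each column sums to h*w).
#' @export
flow_hist <- function(flow, bins) {
  np <- dim(flow)[3]
  out <- matrix(0L, bins$n_bins, np)
  edges <- bins$edges
  for (f in seq_len(np)) {
    v <- as.numeric(flow[, , f])
    ix <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    out[, f] <- tabulate(ix, nbins = bins$n_bins)
  }
  out
}
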