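# Per-frame spatial and colour metrics: rotationally averaged power spectra,
# local contrast, image gradients, and HSV/CIELAB colour channels.

#' Rotationally averaged power spectrum of a clip
#'
#' Per grayscale frame, the 2-D power spectrum is averaged over annuli of
#' integer radial frequency 0..32 cycles/image.
#'
#' @param clip a `movie_clip`.
#' @return a 33 x n_frames matrix.
#' @export
power_spectrum <- function(clip) {
  g <- clip_gray(clip)
  h <- dim(g)[2]
  w <- dim(g)[3]
  kx <- c(0:(w / 2), -(w / 2 - 1):-1)
  ky <- c(0:(h / 2), -(h / 2 - 1):-1)
  r <- round(sqrt(outer(ky^2, kx^2, "+")))
  keep <- r <= 32
  rf <- factor(r[keep], levels = 0:32)
  out <- matrix(0, 33, dim(g)[1])
  for (f in seq_len(dim(g)[1])) {
    p <- Mod(stats::fft(g[f, , ]))^2
    out[, f] <- tapply(p[keep], rf, mean)
  }
  out[is.na(out)] <- 0
  out
}

# Shift a matrix by (dy, dx) with edge replication.
shift_pad <- function(m, dy, dx) {
  h <- nrow(m)
  w <- ncol(m)
  yi <- clamp(seq_len(h) + dy, 1, h)
  xi <- clamp(seq_len(w) + dx, 1, w)
  m[yi, xi, drop = FALSE]
}

#' Local contrast of a clip
#'
#' Per-pixel range (max minus min) of the 3x3 neighbourhood of the grayscale
#' frame, with edge replication at the borders.
#'
#' @param clip a `movie_clip`.
#' @return an h x w x n_frames array.
#' @export
local_contrast <- function(clip) {
  g <- clip_gray(clip)
  nf <- dim(g)[1]
  out <- array(0, c(dim(g)[2], dim(g)[3], nf))
  for (f in seq_len(nf)) {
    m <- g[f, , ]
    mx <- m
    mn <- m
    for (dy in -1:1) {
      for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        s <- shift_pad(m, dy, dx)
        mx <- pmax(mx, s)
        mn <- pmin(mn, s)
      }
    }
    out[, , f] <- mx - mn
  }
  out
}

#' Image gradient magnitude of a clip
#'
#' Central-difference gradients (one-sided at the borders) of the grayscale
#' frames, combined as the gradient magnitude.
#'
#' @param clip a `movie_clip`.
#' @return an h x w x n_frames array.
#' @export
image_gradient <- function(clip) {
  g <- clip_gray(clip)
  nf <- dim(g)[1]
  out <- array(0, c(dim(g)[2], dim(g)[3], nf))
  for (f in seq_len(nf)) {
    gx <- central_diff(g[f, , ], 2)
    gy <- central_diff(g[f, , ], 1)
    out[, , f] <- sqrt(gx^2 + gy^2)
  }
  out
}

#' Colour channel maps of a clip
#'
#' The saturation channel of the HSV representation and the L*, a*, b*
#' channels of CIE 1976 L*a*b* (sRGB primaries, D65 white point).
#'
#' @param clip a `movie_clip` with values in `[0, 1]`.
#' @return a list of four h x w x n_frames arrays: `s_hsv`, `l_lab`,
#'   `a_lab`, `b_lab`.
#' @export
colour_channels <- function(clip) {
  d <- dim(clip)
  nf <- d[1]
  hw <- d[2] * d[3]
  s_hsv <- l_lab <- a_lab <- b_lab <- array(0, c(d[2], d[3], nf))
  for (f in seq_len(nf)) {
    m <- matrix(clip[f, , , ], hw, 3)
    mx <- pmax(m[, 1], m[, 2], m[, 3])
    mn <- pmin(m[, 1], m[, 2], m[, 3])
    s <- ifelse(mx > 0, (mx - mn) / mx, 0)
    lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
    s_hsv[, , f] <- s
    l_lab[, , f] <- lab[, 1]
    a_lab[, , f] <- lab[, 2]
    b_lab[, , f] <- lab[, 3]
  }
  list(s_hsv = s_hsv, l_lab = l_lab, a_lab = a_lab, b_lab = b_lab)
}
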