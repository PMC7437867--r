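# Filter-bank descriptors: GIST, spatiotemporal motion energy, dense SIFT and
# texture statistics. All spatial filtering runs in the Fourier domain with a
# cached Gabor bank.

# Frequency-domain Gabor bank: `n_orient` orientations x `n_scale` scales on
# an h x w grid. Returns a list of complex transfer functions (unshifted
# frequency layout, ready to multiply with fft(image)).
gabor_bank_fft <- function(h = 64, w = 64, n_orient = 8, n_scale = 4,
                           f_max = 0.32) {
  key <- paste(h, w, n_orient, n_scale, f_max, sep = "_")
  if (!is.null(.bank_cache[[key]])) return(.bank_cache[[key]])
  fx <- c(0:(w / 2), -(w / 2 - 1):-1) / w
  fy <- c(0:(h / 2), -(h / 2 - 1):-1) / h
  FX <- matrix(fx, h, w, byrow = TRUE)
  FY <- matrix(fy, h, w)
  rad <- sqrt(FX^2 + FY^2)
  theta <- atan2(FY, FX)
  bank <- list()
  freqs <- f_max / 2^(seq_len(n_scale) - 1)
  for (s in seq_len(n_scale)) {
    f0 <- freqs[s]
    sf <- f0 / 2.5
    for (o in seq_len(n_orient)) {
      ang <- (o - 1) * pi / n_orient
      # angular distance wrapped to [-pi, pi]; one-sided filter in frequency
      dth <- atan2(sin(theta - ang), cos(theta - ang))
      g <- exp(-((rad - f0)^2) / (2 * sf^2)) * exp(-(dth^2) / (2 * 0.45^2))
      bank[[length(bank) + 1]] <- list(scale = s, orient = o, f0 = f0, tf = g)
    }
  }
  out <- list(h = h, w = w, n_orient = n_orient, n_scale = n_scale,
              filters = bank)
  .bank_cache[[key]] <- out
  out
}

.bank_cache <- new.env(parent = emptyenv())

# Complex band responses of one grayscale frame under the bank (list of h x w
# complex matrices; modulus = local energy envelope).
bank_responses <- function(frame, bank) {
  Fm <- stats::fft(frame)
  lapply(bank$filters, function(f) {
    stats::fft(Fm * f$tf, inverse = TRUE) / length(frame)
  })
}

# Mean over a gg x gg grid of spatial cells (h and w divisible by gg).
grid_pool <- function(m, gg = 4) {
  h <- nrow(m)
  w <- ncol(m)
  ch <- h %/% gg
  cw <- w %/% gg
  a <- array(m, c(ch, gg, cw, gg))
  as.vector(apply(a, c(2, 4), mean))
}

#' GIST descriptor of a clip
#'
#' Per frame, the energy (modulus) of a bank of 32 Gabor filters (4 scales x
#' 8 orientations) averaged over a 4 x 4 spatial grid: 512 numbers per frame
#' summarising the global spatial layout of orientations and scales.
#'
#' @param clip a `movie_clip`.
#' @return a 512 x n_frames matrix.
#' @export
gist <- function(clip) {
  g <- clip_gray(clip)
  bank <- gabor_bank_fft(dim(g)[2], dim(g)[3], n_orient = 8, n_scale = 4)
  nf <- dim(g)[1]
  out <- matrix(0, 16 * length(bank$filters), nf)
  for (f in seq_len(nf)) {
    rs <- bank_responses(g[f, , ], bank)
    out[, f] <- unlist(lapply(rs, function(r) grid_pool(Mod(r), 4)))
  }
  out
}

# Temporal quadrature kernels (complex exponential under a Gaussian window).
temporal_kernels <- function(tf = c(0.125, 0.25), len = 9, sd = 2.2) {
  tt <- seq_len(len) - (len + 1) / 2
  lapply(tf, function(f0) exp(2i * pi * f0 * tt) * exp(-tt^2 / (2 * sd^2)))
}

#' Spatiotemporal motion-energy descriptor of a clip
#'
#' Quadrature spatiotemporal filtering: complex Gabor responses at 4
#' orientations x 2 spatial scales are filtered in time by quadrature
#' temporal kernels at 2 temporal frequencies; opponent combinations give
#' direction-selective energies (2 directions), pooled over a 2 x 2 spatial
#' grid. The default bank yields 128 channels per frame; the bank size is a
#' configuration choice recorded in the metric registry.
#'
#' @param clip a `movie_clip`.
#' @param n_orient,n_scale spatial bank size.
#' @return a W x n_frames matrix (W = n_orient*n_scale*2*2*4 at defaults).
#' @export
motion_energy <- function(clip, n_orient = 4, n_scale = 2) {
  g <- clip_gray(clip)
  nf <- dim(g)[1]
  h <- dim(g)[2]
  w <- dim(g)[3]
  bank <- gabor_bank_fft(h, w, n_orient = n_orient, n_scale = n_scale)
  tks <- temporal_kernels()
  # spatial complex responses per frame per filter
  sp <- lapply(seq_len(nf), function(f) bank_responses(g[f, , ], bank))
  nfilt <- length(bank$filters)
  out <- NULL
  half <- (length(tks[[1]]) - 1) / 2
  for (b in seq_len(nfilt)) {
    # (h*w, frames) complex matrix for this spatial channel
    S <- vapply(seq_len(nf), function(f) as.vector(sp[[f]][[b]]),
                complex(h * w))
    for (tk in tks) {
      # temporal convolution, same length (edge truncated)
      Tp <- matrix(0 + 0i, h * w, nf)
      Tm <- matrix(0 + 0i, h * w, nf)
      for (j in seq_along(tk)) {
        lag <- j - half - 1
        src <- clamp(seq_len(nf) + lag, 1, nf)
        Tp <- Tp + S[, src, drop = FALSE] * tk[j]
        Tm <- Tm + S[, src, drop = FALSE] * Conj(tk[j])
      }
      # opponent direction energies, pooled on a 2x2 grid
      e1 <- Mod(Tp)^2
      e2 <- Mod(Tm)^2
      p1 <- apply(e1, 2, function(v) grid_pool(matrix(v, h, w), 2))
      p2 <- apply(e2, 2, function(v) grid_pool(matrix(v, h, w), 2))
      out <- rbind(out, p1, p2)
    }
  }
  out
}

#' Dense SIFT-style descriptors of a clip
#'
#' Per frame, gradient-orientation histograms (8 bins) over 4 x 4 subcells of
#' 16 keypoints on a regular 4 x 4 grid, L2-normalised with the standard 0.2
#' clamping: 16 x 128 = 2048 numbers per frame.
#'
#' @param clip a `movie_clip`.
#' @return a 2048 x n_frames matrix.
#' @export
sift_dense <- function(clip) {
  g <- clip_gray(clip)
  nf <- dim(g)[1]
  h <- dim(g)[2]
  w <- dim(g)[3]
  cell <- 4 # subcell size in px
  ncell <- h / cell # 16 subcells per side
  out <- matrix(0, 16 * 128, nf)
  cy <- rep(ceiling(seq_len(h) / cell), w)
  cx <- rep(ceiling(seq_len(w) / cell), each = h)
  cid <- cy + (cx - 1) * ncell
  for (f in seq_len(nf)) {
    m <- g[f, , ]
    gx <- central_diff(m, 2)
    gy <- central_diff(m, 1)
    mag <- as.vector(sqrt(gx^2 + gy^2))
    ori <- as.vector(atan2(gy, gx)) # (-pi, pi]
    bin <- pmin(8L, 1L + floor((ori + pi) / (2 * pi / 8)))
    # subcell x orientation histogram (256 subcells x 8 bins)
    hist <- rowsum(mag * outer(bin, 1:8, "=="), group = cid)
    desc <- numeric(16 * 128)
    # assemble per-keypoint descriptors: keypoint (i,j) covers subcells
    # rows 4(i-1)+1..4i, cols 4(j-1)+1..4j
    k <- 0
    for (j in 1:4) {
      for (i in 1:4) {
        rows <- as.vector(outer(4 * (i - 1) + 1:4, (4 * (j - 1) + 1:4 - 1) * ncell, "+"))
        v <- as.vector(t(hist[rows, , drop = FALSE]))
        nrm <- sqrt(sum(v^2))
        if (nrm > 0) {
          v <- pmin(v / nrm, 0.2)
          v <- v / max(sqrt(sum(v^2)), 1e-12)
        }
        desc[k * 128 + seq_len(128)] <- v
        k <- k + 1
      }
    }
    out[, f] <- desc
  }
  out
}

#' Texture statistics of a clip
#'
#' A compact set of texture summary statistics per frame, in the spirit of
#' parametric texture models built on oriented multi-scale decompositions:
#' grayscale marginal moments, per-band magnitude means and variances (3
#' scales x 4 orientations), local autocorrelations of the band magnitudes,
#' cross-orientation and cross-scale magnitude correlations, and colour
#' channel moments and correlations.
#'
#' @param clip a `movie_clip`.
#' @return a K x n_frames matrix (K = 119 at defaults).
#' @export
ps_texture <- function(clip) {
  g <- clip_gray(clip)
  nf <- dim(g)[1]
  h <- dim(g)[2]
  w <- dim(g)[3]
  bank <- gabor_bank_fft(h, w, n_orient = 4, n_scale = 3)
  nb <- length(bank$filters) # 12
  out <- NULL
  skew <- function(x) mean((x - mean(x))^3) / max(stats::sd(x), 1e-12)^3
  kurt <- function(x) mean((x - mean(x))^4) / max(stats::sd(x), 1e-12)^4
  for (f in seq_len(nf)) {
    m <- g[f, , ]
    rs <- bank_responses(m, bank)
    mags <- lapply(rs, Mod)
    v <- c(mean(m), stats::var(as.vector(m)), skew(as.vector(m)),
           kurt(as.vector(m)), min(m), max(m))
    # lowpass residual moments at two blur levels
    lp1 <- box_sum(m, 2) / 25
    lp2 <- box_sum(m, 5) / 121
    v <- c(v, stats::var(as.vector(lp1)), skew(as.vector(lp1)), kurt(as.vector(lp1)),
           stats::var(as.vector(lp2)), skew(as.vector(lp2)), kurt(as.vector(lp2)))
    # band magnitude moments
    v <- c(v, unlist(lapply(mags, function(mm) c(mean(mm), stats::var(as.vector(mm))))))
    # central autocorrelation of each band magnitude (lags (0,1),(1,0),(1,1),(1,-1))
    for (mm in mags) {
      mc <- mm - mean(mm)
      den <- sum(mc^2) + 1e-12
      v <- c(v,
             sum(mc[, -1] * mc[, -w]) / den,
             sum(mc[-1, ] * mc[-h, ]) / den,
             sum(mc[-1, -1] * mc[-h, -w]) / den,
             sum(mc[-1, -w] * mc[-h, -1]) / den)
    }
    # cross-orientation correlations within each scale
    for (s in seq_len(bank$n_scale)) {
      ix <- which(vapply(bank$filters, function(ff) ff$scale == s, logical(1)))
      for (a in seq_along(ix)) {
        for (b in seq_along(ix)) {
          if (b <= a) next
          v <- c(v, stats::cor(as.vector(mags[[ix[a]]]), as.vector(mags[[ix[b]]])))
        }
      }
    }
    # cross-scale correlations, same orientation, adjacent scales
    for (s in seq_len(bank$n_scale - 1)) {
      for (o in seq_len(bank$n_orient)) {
        i1 <- which(vapply(bank$filters, function(ff) ff$scale == s && ff$orient == o, logical(1)))
        i2 <- which(vapply(bank$filters, function(ff) ff$scale == s + 1 && ff$orient == o, logical(1)))
        v <- c(v, stats::cor(as.vector(mags[[i1]]), as.vector(mags[[i2]])))
      }
    }
    # colour moments and channel correlations
    ch <- matrix(clip[f, , , ], h * w, 3)
    v <- c(v, colMeans(ch), apply(ch, 2, stats::var),
           stats::cor(ch[, 1], ch[, 2]), stats::cor(ch[, 1], ch[, 3]),
           stats::cor(ch[, 2], ch[, 3]))
    v[!is.finite(v)] <- 0
    out <- cbind(out, v)
  }
  dimnames(out) <- NULL
  out
}
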