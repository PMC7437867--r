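# Minimal convolutional engine: im2col convolution via BLAS, 2x2 max pooling,
# ReLU and fully connected layers, each with a hand-derived backward pass.
# Feature maps are stored as matrices of shape (h*w*channels, n_columns) with
# row layout y-fastest, then x, then channel; columns are independent samples
# (clip x pathway combinations), which lets parallel slow-fusion pathways with
# shared filter banks ride along the batch dimension.

# Geometry (index tables) for one conv layer; computed once per model.
conv_geom <- function(h, w, c_in, k, stride, pad) {
  hp <- h + 2 * pad
  wp <- w + 2 * pad
  out_h <- (hp - k) %/% stride + 1
  out_w <- (wp - k) %/% stride + 1
  K <- k * k * c_in
  P <- out_h * out_w
  # rows of the padded input participating in each patch
  off <- as.vector(outer(
    seq_len(k),
    (seq_len(k) - 1) * hp,
    "+"
  )) # k x k spatial offsets within one channel
  off <- as.vector(outer(off, (seq_len(c_in) - 1) * hp * wp, "+")) # K offsets
  oy <- rep(seq_len(out_h), out_w)
  ox <- rep(seq_len(out_w), each = out_h)
  tl <- (oy - 1) * stride + ((ox - 1) * stride) * hp # top-left corner, 0-based
  idx <- outer(off, tl, "+") # K x P
  storage.mode(idx) <- "integer"
  # interior rows (non-padding) of the padded layout
  iy <- rep(seq_len(h) + pad, w * c_in)
  ix <- rep(rep(seq_len(w) + pad - 1, each = h), c_in)
  ic <- rep(seq_len(c_in) - 1, each = h * w)
  interior <- iy + ix * hp + ic * hp * wp
  # sparse scatter matrix for the backward col2im accumulation
  scat <- Matrix::sparseMatrix(
    i = as.vector(idx), j = seq_len(K * P),
    x = 1, dims = c(hp * wp * c_in, K * P)
  )
  list(
    h = h, w = w, c_in = c_in, k = k, stride = stride, pad = pad,
    hp = hp, wp = wp, out_h = out_h, out_w = out_w, K = K, P = P,
    idx = idx, interior = as.integer(interior), scatter = scat
  )
}

conv_pad <- function(x, g) {
  if (g$pad == 0) return(x)
  xp <- matrix(0, g$hp * g$wp * g$c_in, ncol(x))
  xp[g$interior, ] <- x
  xp
}

# Forward convolution. W: (K x C); returns activation (out_h*out_w*C, N) and
# a cache for the backward pass.
conv_forward <- function(x, W, b, g) {
  n <- ncol(x)
  xp <- conv_pad(x, g)
  cols <- xp[g$idx, , drop = FALSE] # (K*P, N)
  dim(cols) <- c(g$K, g$P * n)
  z <- crossprod(W, cols) + b # (C, P*N)
  zz <- array(z, c(ncol(W), g$P, n))
  out <- aperm(zz, c(2, 1, 3)) # (P, C, N)
  dim(out) <- c(g$P * ncol(W), n)
  list(out = out, cols = cols, n = n)
}

# Backward convolution. d: gradient wrt output in (P*C, N) layout.
conv_backward <- function(d, W, g, cache, need_dx = TRUE) {
  n <- cache$n
  C <- ncol(W)
  dd <- array(d, c(g$P, C, n))
  dz <- aperm(dd, c(2, 1, 3)) # (C, P, N)
  dim(dz) <- c(C, g$P * n)
  dW <- cache$cols %*% t(dz) # (K, C)
  db <- rowSums(dz)
  dx <- NULL
  if (need_dx) {
    dcols <- W %*% dz # (K, P*N)
    dim(dcols) <- c(g$K * g$P, n)
    dxp <- as.matrix(g$scatter %*% dcols)
    dx <- dxp[g$interior, , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# 2x2 max pooling on (h*w*c, N); h and w must be even.
pool_forward <- function(x, h, w, c) {
  n <- ncol(x)
  stopifnot(h %% 2 == 0, w %% 2 == 0)
  h2 <- h %/% 2
  w2 <- w %/% 2
  a <- array(x, c(2, h2, w, c * n))
  m1a <- a[1, , , , drop = FALSE]
  dim(m1a) <- c(h2, w, c * n)
  m1b <- a[2, , , , drop = FALSE]
  dim(m1b) <- c(h2, w, c * n)
  k1 <- m1a >= m1b
  m1 <- pmax(m1a, m1b) # (h2, w, cN)
  b <- array(m1, c(h2, 2, w2, c * n))
  m2a <- b[, 1, , , drop = FALSE]
  dim(m2a) <- c(h2, w2, c * n)
  m2b <- b[, 2, , , drop = FALSE]
  dim(m2b) <- c(h2, w2, c * n)
  k2 <- m2a >= m2b
  out <- pmax(m2a, m2b)
  dim(out) <- c(h2 * w2 * c, n)
  list(out = out, k1 = k1, k2 = k2, h = h, w = w, c = c, n = n)
}

pool_backward <- function(d, cache) {
  h2 <- cache$h %/% 2
  w2 <- cache$w %/% 2
  cn <- cache$c * cache$n
  dd <- array(d, c(h2, w2, cn))
  b <- array(0, c(h2, 2, w2, cn))
  b[, 1, , ] <- dd * cache$k2
  b[, 2, , ] <- dd * !cache$k2
  m1 <- array(b, c(h2, cache$w, cn))
  a <- array(0, c(2, h2, cache$w, cn))
  a[1, , , ] <- m1 * cache$k1
  a[2, , , ] <- m1 * !cache$k1
  dim(a) <- c(cache$h * cache$w * cache$c, cache$n)
  a
}

relu_forward <- function(x) pmax(x, 0)

# Zero the rows of the given channels (after ReLU); rows are contiguous per
# channel in the (h*w*c, N) layout.
lesion_rows <- function(channels, h, w) {
  if (!length(channels)) return(integer(0))
  as.vector(vapply(channels, function(ch) ((ch - 1) * h * w + 1):(ch * h * w),
                   integer(h * w)))
}
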