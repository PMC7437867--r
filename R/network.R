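# The slow-fusion video regression network.
#
# Three convolutional stages with parallel temporal pathways that fuse over
# depth (stage 1 sees 8-frame windows at stride 4, stage 2 fuses adjacent
# stage-1 pathways into 12-frame windows, stage 3 fuses everything and sees
# all 20 frames), followed by a fully connected layer, dropout and a single
# linear regression output. Filter banks are shared across the parallel
# pathways of a stage by default, so a "unit" is one filter whose response
# concatenates its activation maps across pathways.

#' Slow-fusion network configuration
#'
#' Defaults follow the reference architecture: temporal extents 8/12/20 with
#' stride 4, 256/64/100 convolutional filters, a 4096-unit fully connected
#' layer, dropout 0.5, and SGD with learning rate 1.110510e-5, momentum
#' 0.43325 and L2 regularisation 4e-9 for 30 epochs. Kernel sizes, spatial
#' strides, pooling and the input downsampling factor are free parameters of
#' the implementation.
#'
#' @param frames,height,width,channels input clip geometry.
#' @param t_extent temporal extents of the three conv stages, in input frames.
#' @param t_stride temporal strides of stages 1 and 2, in input frames.
#' @param conv_channels filters per conv stage.
#' @param kernel square spatial kernel size per conv stage.
#' @param conv_stride spatial stride per conv stage.
#' @param input_pool spatial average-pooling factor applied to the input
#'   (1 = none).
#' @param fc4_width units in the fully connected layer FC4.
#' @param dropout dropout probability after FC4.
#' @param learning_rate,momentum,l2 SGD hyperparameters.
#' @param epochs default training epochs.
#' @param batch_size minibatch size.
#' @param share_pathway_filters share one filter bank across the parallel
#'   pathways of a stage (default) or give each pathway its own bank.
#' @return a `slowfusion_config` list.
#' @export
slowfusion_config <- function(frames = 20L, height = 64L, width = 64L,
                              channels = 3L,
                              t_extent = c(8L, 12L, 20L), t_stride = c(4L, 4L),
                              conv_channels = c(256L, 64L, 100L),
                              kernel = c(5L, 3L, 3L),
                              conv_stride = c(2L, 1L, 1L),
                              input_pool = 1L,
                              fc4_width = 4096L,
                              dropout = 0.5,
                              learning_rate = 1.110510e-5,
                              momentum = 0.43325,
                              l2 = 4e-9,
                              epochs = 30L,
                              batch_size = 16L,
                              share_pathway_filters = TRUE) {
  cfg <- list(
    frames = as.integer(frames), height = as.integer(height),
    width = as.integer(width), channels = as.integer(channels),
    t_extent = as.integer(t_extent), t_stride = as.integer(t_stride),
    conv_channels = as.integer(conv_channels), kernel = as.integer(kernel),
    conv_stride = as.integer(conv_stride), input_pool = as.integer(input_pool),
    fc4_width = as.integer(fc4_width), dropout = dropout,
    learning_rate = learning_rate, momentum = momentum, l2 = l2,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    share_pathway_filters = isTRUE(share_pathway_filters)
  )
  if ((cfg$frames - cfg$t_extent[1]) %% cfg$t_stride[1] != 0) {
    stop("config error: stage-1 windows at the given stride do not tile the ",
         cfg$frames, " input frames")
  }
  n1 <- (cfg$frames - cfg$t_extent[1]) %/% cfg$t_stride[1] + 1L
  if (cfg$t_extent[2] != cfg$t_extent[1] + cfg$t_stride[1] ||
      cfg$t_stride[2] != cfg$t_stride[1]) {
    stop("config error: stage-2 extent/stride must fuse adjacent stage-1 pathways")
  }
  if (cfg$t_extent[3] != cfg$frames) {
    stop("config error: stage 3 must cover the full frame range")
  }
  if (n1 < 2) stop("config error: need at least two stage-1 pathways")
  cfg$n_pathways <- c(n1, n1 - 1L, 1L)
  if (cfg$fc4_width < 1) stop("config error: fc4_width must be >= 1")
  structure(cfg, class = "slowfusion_config")
}

#' Temporal receptive field of a network stage
#'
#' Number of distinct input frames that influence one unit of the given
#' stage: stage 1 sees its own temporal window, stage 2 the union of two
#' adjacent stage-1 windows, stages 3 and 4 (FC) the full sequence.
#'
#' @param config a [slowfusion_config()].
#' @param stage stage index in 1..4.
#' @return frame count.
#' @export
#' @examples
#' temporal_receptive_field(slowfusion_config(), 2) # 12
temporal_receptive_field <- function(config = slowfusion_config(), stage) {
  if (!stage %in% 1:4) stop("unknown stage: ", stage)
  switch(stage,
    config$t_extent[1],
    config$t_extent[1] + config$t_stride[1],
    config$frames,
    config$frames
  )
}

# Spatial geometry chain of the three conv stages.
sf_geometry <- function(cfg) {
  h0 <- cfg$height %/% cfg$input_pool
  w0 <- cfg$width %/% cfg$input_pool
  cin <- c(
    cfg$channels * cfg$t_extent[1],
    2L * cfg$conv_channels[1],
    cfg$n_pathways[2] * cfg$conv_channels[2]
  )
  g <- vector("list", 3)
  h <- h0
  w <- w0
  for (s in 1:3) {
    pad <- (cfg$kernel[s] - 1L) %/% 2L
    g[[s]] <- conv_geom(h, w, cin[s], cfg$kernel[s], cfg$conv_stride[s], pad)
    if (g[[s]]$out_h %% 2 != 0 || g[[s]]$out_w %% 2 != 0) {
      stop("config error: conv stage ", s, " output is not poolable (",
           g[[s]]$out_h, "x", g[[s]]$out_w, ")")
    }
    h <- g[[s]]$out_h %/% 2L
    w <- g[[s]]$out_w %/% 2L
  }
  list(g = g, h0 = h0, w0 = w0, fc_in = h * w * cfg$conv_channels[3])
}

#' Build a slow-fusion network with random initial weights
#'
#' @param config a [slowfusion_config()].
#' @param seed integer seed for the weight initialisation (same seed, same
#'   initial weights).
#' @return a `slowfusion` model object with a conv-unit registry.
#' @export
build_network <- function(config = slowfusion_config(), seed = 1L) {
  geo <- sf_geometry(config)
  r <- rng_stream(derive_seed(seed, 42L))
  he <- function(K, C, P = 1L) {
    w <- array(r$norm(K * C * P, 0, sqrt(2 / K)), c(K, C, P))
    if (P == 1L) dim(w) <- c(K, C)
    w
  }
  P <- if (config$share_pathway_filters) c(1L, 1L) else config$n_pathways[1:2]
  params <- list(
    W1 = he(geo$g[[1]]$K, config$conv_channels[1], P[1]),
    b1 = numeric(config$conv_channels[1]),
    W2 = he(geo$g[[2]]$K, config$conv_channels[2], P[2]),
    b2 = numeric(config$conv_channels[2]),
    W3 = he(geo$g[[3]]$K, config$conv_channels[3]),
    b3 = numeric(config$conv_channels[3]),
    W4 = matrix(r$norm(geo$fc_in * config$fc4_width, 0, sqrt(2 / geo$fc_in)),
                geo$fc_in, config$fc4_width),
    b4 = numeric(config$fc4_width),
    W5 = matrix(r$norm(config$fc4_width, 0, sqrt(1 / config$fc4_width)),
                config$fc4_width, 1),
    b5 = 8.5 # centre of the 1..16 label scale
  )
  registry <- data.frame(
    unit = seq_len(sum(config$conv_channels)),
    layer = rep(1:3, config$conv_channels),
    channel = unlist(lapply(config$conv_channels, seq_len))
  )
  m <- structure(
    list(config = config, geom = geo, params = params,
         mean_pixel = 0.5, lesion = integer(0), registry = registry),
    class = "slowfusion"
  )
  m$path_idx <- sf_pathway_index(config, geo)
  m$input_idx <- sf_input_index(config, geo, m$path_idx)
  m
}

#' @export
print.slowfusion <- function(x, ...) {
  cfg <- x$config
  cat("Slow-fusion network\n")
  cat(sprintf("  input: %d frames, %d x %d x %d (input pool %d)\n",
              cfg$frames, cfg$height, cfg$width, cfg$channels, cfg$input_pool))
  cat(sprintf("  conv stages: %s filters, %s pathways, kernels %s\n",
              paste(cfg$conv_channels, collapse = "/"),
              paste(cfg$n_pathways, collapse = "/"),
              paste(cfg$kernel, collapse = "/")))
  cat(sprintf("  FC4: %d units, dropout %.2f; %d registered conv units\n",
              cfg$fc4_width, cfg$dropout, nrow(x$registry)))
  if (length(x$lesion)) {
    cat(sprintf("  lesioned units: %d\n", length(x$lesion)))
  }
  invisible(x)
}

# -- forward pass -------------------------------------------------------------

# Pathway gather index: maps the centred, downsampled input column
# (h0*w0*channels*frames) onto the stacked stage-1 pathway inputs
# (h0*w0*channels*T1, P1). Input row layout of the source: (frame fastest,
# then y, x, colour) is rearranged so that within a pathway the conv channel
# order is colour-fastest, then frame.
sf_pathway_index <- function(cfg, geo) {
  h0 <- geo$h0
  w0 <- geo$w0
  nc <- cfg$channels
  T1 <- cfg$t_extent[1]
  P1 <- cfg$n_pathways[1]
  Fn <- cfg$frames
  # source index for (y, x, colour, frame): clip array layout is (f, y, x, c)
  src <- function(f, y, x, cc) f + (y - 1) * Fn + (x - 1) * Fn * h0 + (cc - 1) * Fn * h0 * w0
  idx <- integer(h0 * w0 * nc * T1 * P1)
  pos <- 1L
  for (p in seq_len(P1)) {
    f0 <- (p - 1L) * cfg$t_stride[1]
    for (tt in seq_len(T1)) {
      for (cc in seq_len(nc)) {
        # whole y-x plane at once
        yx <- outer(seq_len(h0), (seq_len(w0) - 1) * h0, "+") # y + (x-1)*h0
        idx[pos:(pos + h0 * w0 - 1)] <- src(f0 + tt, 1, 1, cc) - 1L +
          (as.vector(yx) - 1L) * Fn + 1L
        pos <- pos + h0 * w0
      }
    }
  }
  matrix(idx, ncol = P1)
}

# Compose the pathway gather with the input average-pooling: one index
# vector per pooling offset, mapping raw clip rows (layout f, y, x, c at full
# resolution) directly onto the stacked stage-1 pathway input rows. The
# stage-1 input of a batch is then the mean of `ip^2` cheap gathers.
sf_input_index <- function(cfg, geo, path_idx) {
  ip <- cfg$input_pool
  Fn <- cfg$frames
  h0 <- geo$h0
  w0 <- geo$w0
  nc <- cfg$channels
  H <- cfg$height
  W <- cfg$width
  pid <- as.vector(path_idx) - 1L # 0-based, into (Fn, h0, w0, nc)
  f <- pid %% Fn
  rest <- pid %/% Fn
  y <- rest %% h0
  rest <- rest %/% h0
  x <- rest %% w0
  cc <- rest %/% w0
  lapply(seq_len(ip * ip), function(k) {
    dy <- (k - 1) %% ip
    dx <- (k - 1) %/% ip
    as.integer(f + (y * ip + dy) * Fn + (x * ip + dx) * Fn * H +
                 cc * Fn * H * W + 1L)
  })
}

# Gather the stage-1 pathway input from a clip batch, averaging over the
# configured input pooling and centring on the training mean pixel. Accepts
# either full-resolution batches or batches already at the pooled resolution
# (detected from the row count), so a pre-downsampled training store can skip
# the averaging.
sf_gather_input <- function(model, X) {
  if (nrow(X) == length(model$path_idx) ||
      nrow(X) == model$config$frames * model$geom$h0 * model$geom$w0 * model$config$channels) {
    return(X[as.vector(model$path_idx), , drop = FALSE] - model$mean_pixel)
  }
  ii <- model$input_idx
  acc <- X[ii[[1]], , drop = FALSE]
  if (length(ii) > 1) {
    for (k in 2:length(ii)) acc <- acc + X[ii[[k]], , drop = FALSE]
  }
  acc / length(ii) - model$mean_pixel
}

# Pre-average a clipset to the model's pooled input resolution (8-bit store;
# the 1/255 quantisation is far below rendering noise). Speeds up training,
# which touches every clip every epoch.
sf_downsample_clipset <- function(cs, cfg) {
  ip <- cfg$input_pool
  if (ip == 1) return(cs)
  Fn <- cfg$frames
  H <- cfg$height
  W <- cfg$width
  nc <- cfg$channels
  h0 <- H %/% ip
  w0 <- W %/% ip
  base <- expand.grid(f = seq_len(Fn) - 1L, y = seq_len(h0) - 1L,
                      x = seq_len(w0) - 1L, c = seq_len(nc) - 1L)
  idx <- lapply(seq_len(ip * ip), function(k) {
    dy <- (k - 1) %% ip
    dx <- (k - 1) %/% ip
    as.integer(base$f + (base$y * ip + dy) * Fn + (base$x * ip + dx) * Fn * H +
                 base$c * Fn * H * W + 1L)
  })
  n <- length(cs)
  out <- matrix(as.raw(0), Fn * h0 * w0 * nc, n)
  for (ch in split(seq_len(n), ceiling(seq_len(n) / 128))) {
    X <- clipset_batch(cs, ch)
    acc <- X[idx[[1]], , drop = FALSE]
    for (k in 2:length(idx)) acc <- acc + X[idx[[k]], , drop = FALSE]
    out[, ch] <- as.raw(round(acc / length(idx) * 255))
  }
  structure(list(data = out, design = cs$design, pooled = ip),
            class = "clipset")
}

# Column indices fusing stage outputs: stage-2 pathway q reads stage-1
# pathways q and q+1; stage 3 reads all stage-2 pathways.
sf_fuse_cols <- function(P_in, P_out, B) {
  lapply(seq_len(P_in - P_out + 1L), function(o) {
    as.vector(outer(seq_len(P_out) + (o - 1L), (seq_len(B) - 1L) * P_in, "+"))
  })
}

stage_conv_forward <- function(x, W, b, g, P, share) {
  if (share || length(dim(W)) == 2L) {
    conv_forward(x, W, b, g)
  } else {
    n <- ncol(x) %/% P
    out <- NULL
    caches <- vector("list", P)
    for (p in seq_len(P)) {
      cols <- seq(p, by = P, length.out = n)
      cf <- conv_forward(x[, cols, drop = FALSE], W[, , p], b, g)
      if (is.null(out)) out <- matrix(0, nrow(cf$out), ncol(x))
      out[, cols] <- cf$out
      caches[[p]] <- cf
    }
    list(out = out, caches = caches, n = ncol(x), per_pathway = TRUE)
  }
}

stage_conv_backward <- function(d, W, g, cache, P, share, need_dx = TRUE) {
  if (share || length(dim(W)) == 2L) {
    conv_backward(d, W, g, cache, need_dx)
  } else {
    n <- cache$n %/% P
    dW <- array(0, dim(W))
    db <- numeric(dim(W)[2])
    dx <- if (need_dx) matrix(0, g$h * g$w * g$c_in, cache$n) else NULL
    for (p in seq_len(P)) {
      cols <- seq(p, by = P, length.out = n)
      bk <- conv_backward(d[, cols, drop = FALSE], W[, , p], g,
                          cache$caches[[p]], need_dx)
      dW[, , p] <- bk$dW
      db <- db + bk$db
      if (need_dx) dx[, cols] <- bk$dx
    }
    list(dx = dx, dW = dW, db = db)
  }
}

# Full forward pass over a batch. X: (20*64*64*3, B) pixel matrix in [0,1].
# Returns predictions, and optionally ReLU activations and backward caches.
sf_forward <- function(model, X, train = FALSE, keep = FALSE,
                       want_acts = FALSE) {
  cfg <- model$config
  geo <- model$geom
  p <- model$params
  B <- ncol(X)
  P1 <- cfg$n_pathways[1]
  P2 <- cfg$n_pathways[2]
  share <- cfg$share_pathway_filters

  x1 <- sf_gather_input(model, X)
  dim(x1) <- c(nrow(model$path_idx), P1 * B)

  les <- model$lesion
  reg <- model$registry
  les_ch <- function(layer) reg$channel[reg$unit %in% les & reg$layer == layer]

  fw <- list(B = B)
  if (keep) fw$x1 <- x1

  # stage 1
  c1 <- stage_conv_forward(x1, p$W1, p$b1, geo$g[[1]], P1, share)
  a1 <- relu_forward(c1$out)
  lr <- lesion_rows(les_ch(1), geo$g[[1]]$out_h, geo$g[[1]]$out_w)
  if (length(lr)) a1[lr, ] <- 0
  p1 <- pool_forward(a1, geo$g[[1]]$out_h, geo$g[[1]]$out_w, cfg$conv_channels[1])
  if (keep) { fw$c1 <- c1; fw$z1 <- c1$out; fw$p1 <- p1 }
  if (want_acts) fw$relu1 <- a1

  # fuse into stage 2
  fu2 <- sf_fuse_cols(P1, P2, B)
  x2 <- rbind(p1$out[, fu2[[1]], drop = FALSE], p1$out[, fu2[[2]], drop = FALSE])
  c2 <- stage_conv_forward(x2, p$W2, p$b2, geo$g[[2]], P2, share)
  a2 <- relu_forward(c2$out)
  lr <- lesion_rows(les_ch(2), geo$g[[2]]$out_h, geo$g[[2]]$out_w)
  if (length(lr)) a2[lr, ] <- 0
  p2 <- pool_forward(a2, geo$g[[2]]$out_h, geo$g[[2]]$out_w, cfg$conv_channels[2])
  if (keep) { fw$fu2 <- fu2; fw$x2 <- x2; fw$c2 <- c2; fw$p2 <- p2 }
  if (want_acts) fw$relu2 <- a2

  # fuse into stage 3 (single pathway)
  fu3 <- lapply(seq_len(P2), function(q) seq(q, by = P2, length.out = B))
  x3 <- do.call(rbind, lapply(fu3, function(cc) p2$out[, cc, drop = FALSE]))
  c3 <- stage_conv_forward(x3, p$W3, p$b3, geo$g[[3]], 1L, TRUE)
  a3 <- relu_forward(c3$out)
  lr <- lesion_rows(les_ch(3), geo$g[[3]]$out_h, geo$g[[3]]$out_w)
  if (length(lr)) a3[lr, ] <- 0
  p3 <- pool_forward(a3, geo$g[[3]]$out_h, geo$g[[3]]$out_w, cfg$conv_channels[3])
  if (keep) { fw$fu3 <- fu3; fw$x3 <- x3; fw$c3 <- c3; fw$p3 <- p3 }
  if (want_acts) fw$relu3 <- a3

  # FC4 -> dropout -> output
  feat <- p3$out
  z4 <- crossprod(p$W4, feat) + p$b4
  a4 <- relu_forward(z4)
  drop <- NULL
  h4 <- a4
  if (train && cfg$dropout > 0) {
    drop <- matrix(stats::runif(length(a4)) >= cfg$dropout, nrow(a4), ncol(a4)) /
      (1 - cfg$dropout)
    h4 <- a4 * drop
  }
  pred <- as.numeric(crossprod(p$W5, h4) + p$b5)
  if (keep) { fw$feat <- feat; fw$z4 <- z4; fw$a4 <- a4; fw$drop <- drop; fw$h4 <- h4 }
  if (want_acts) fw$relu4 <- a4
  fw$pred <- pred
  fw
}

# Backward pass for training: gradient of mean squared error wrt parameters.
sf_backward <- function(model, fw, dpred) {
  cfg <- model$config
  geo <- model$geom
  p <- model$params
  B <- fw$B
  share <- cfg$share_pathway_filters
  g1 <- geo$g[[1]]; g2 <- geo$g[[2]]; g3 <- geo$g[[3]]

  dh4 <- p$W5 %*% matrix(dpred, 1, B) # (F, B)
  gW5 <- fw$h4 %*% matrix(dpred, B, 1)
  gb5 <- sum(dpred)
  da4 <- if (is.null(fw$drop)) dh4 else dh4 * fw$drop
  dz4 <- da4 * (fw$z4 > 0)
  gW4 <- fw$feat %*% t(dz4)
  gb4 <- rowSums(dz4)
  dfeat <- p$W4 %*% dz4

  da3 <- pool_backward(dfeat, fw$p3)
  dz3 <- da3 * (fw$c3$out > 0)
  bk3 <- stage_conv_backward(dz3, p$W3, g3, fw$c3, 1L, TRUE)
  # un-fuse stage-3 input back onto stage-2 pathway outputs
  dp2 <- matrix(0, nrow(fw$p2$out), ncol(fw$p2$out))
  rows_per <- nrow(fw$p2$out)
  for (q in seq_along(fw$fu3)) {
    dp2[, fw$fu3[[q]]] <- bk3$dx[((q - 1) * rows_per + 1):(q * rows_per), , drop = FALSE]
  }

  da2 <- pool_backward(dp2, fw$p2)
  dz2 <- da2 * (fw$c2$out > 0)
  bk2 <- stage_conv_backward(dz2, p$W2, g2, fw$c2, cfg$n_pathways[2], share)
  dp1 <- matrix(0, nrow(fw$p1$out), ncol(fw$p1$out))
  half <- nrow(fw$p1$out)
  dp1[, fw$fu2[[1]]] <- bk2$dx[1:half, , drop = FALSE]
  dp1[, fw$fu2[[2]]] <- dp1[, fw$fu2[[2]], drop = FALSE] +
    bk2$dx[(half + 1):(2 * half), , drop = FALSE]

  da1 <- pool_backward(dp1, fw$p1)
  dz1 <- da1 * (fw$c1$out > 0)
  bk1 <- stage_conv_backward(dz1, p$W1, g1, fw$c1, cfg$n_pathways[1], share,
                             need_dx = FALSE)

  list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW, b2 = bk2$db,
       W3 = bk3$dW, b3 = bk3$db, W4 = gW4, b4 = gb4,
       W5 = gW5, b5 = gb5)
}
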