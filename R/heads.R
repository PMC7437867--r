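# Linear decoders and frozen-prefix head retraining: per-layer readouts, the
# FC4 capacity-compression experiment and scene-transfer learning.

#' Fit a linear decoder on activations
#'
#' A single linear readout trained by full-batch gradient descent on the
#' mean squared error, with an 80/20 train/held-out split; reports the
#' held-out RMSE on the rating scale. Zero-variance feature columns are
#' tolerated (they receive zero weight) with a warning.
#'
#' @param activations stimuli x features matrix.
#' @param targets numeric targets (rating scale).
#' @param epochs gradient steps (default 300).
#' @param lr learning rate as a fraction of the inverse largest curvature
#'   (the top eigenvalue of the feature covariance, estimated by power
#'   iteration), which keeps full-batch descent stable for any width.
#' @param holdout fraction of stimuli held out.
#' @param seed split/initialisation seed.
#' @return a `linear_decoder`: list with `w`, `b`, feature scaling, `rmse`
#'   (held-out) and the split indices.
#' @export
fit_linear_decoder <- function(activations, targets, epochs = 300, lr = 0.1,
                               holdout = 0.2, seed = 1L) {
  X <- as.matrix(activations)
  stopifnot(nrow(X) == length(targets))
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) warning("degenerate (zero-variance) activation column(s)")
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  r <- rng_stream(derive_seed(seed, 4004L))
  n <- nrow(X)
  test <- sort(unique(r$int(max(1, round(holdout * n)), n)))
  train <- setdiff(seq_len(n), test)
  w <- numeric(ncol(X))
  b <- mean(targets[train])
  Xt <- Xs[train, , drop = FALSE]
  yt <- targets[train]
  # top eigenvalue of X'X/n by power iteration sets the stable step size
  v <- r$norm(ncol(Xt))
  v <- v / sqrt(sum(v^2))
  lam <- 1
  for (it in 1:15) {
    u <- as.numeric(crossprod(Xt, Xt %*% v)) / nrow(Xt)
    lam <- sqrt(sum(u^2))
    if (lam <= 0) break
    v <- u / lam
  }
  step <- lr / max(lam, 1e-8)
  for (e in seq_len(epochs)) {
    pred <- as.numeric(Xt %*% w) + b
    err <- pred - yt
    gw <- as.numeric(crossprod(Xt, err)) / length(yt) + 1e-4 * w
    gb <- mean(err)
    w <- w - step * gw
    b <- b - lr * gb
  }
  pred_test <- as.numeric(Xs[test, , drop = FALSE] %*% w) + b
  structure(
    list(w = w, b = b, mu = mu, sd = sdv,
         rmse = rmse(pred_test, targets[test]),
         train = train, test = test),
    class = "linear_decoder"
  )
}

#' @export
predict.linear_decoder <- function(object, activations, ...) {
  Xs <- sweep(sweep(as.matrix(activations), 2, object$mu), 2, object$sd, "/")
  as.numeric(Xs %*% object$w) + object$b
}

# Cached stage-3 output features (the frozen-prefix representation feeding
# FC4) for a clip source.
sf_prefix_features <- function(model, clips, batch = 64L) {
  src <- clips_source(clips)
  out <- NULL
  for (ch in split(seq_len(src$n), ceiling(seq_len(src$n) / batch))) {
    fw <- sf_forward(model, src$get(ch), keep = TRUE)
    out <- cbind(out, fw$feat)
  }
  out # (fc_in, n)
}

# Train an FC head (width -> ReLU -> dropout -> linear output) on cached
# prefix features by SGD with momentum. Returns weights and validation RMSE.
train_fc_head <- function(feat, y, width, val_idx, val_targets, epochs = 30,
                          lr = 1e-3, momentum = 0.9, dropout = 0.2,
                          batch = 64L, seed = 1L) {
  n <- ncol(feat)
  d <- nrow(feat)
  tr <- setdiff(seq_len(n), val_idx)
  r <- rng_stream(derive_seed(seed, 8008L))
  W1 <- matrix(r$norm(d * width, 0, sqrt(2 / d)), d, width)
  b1 <- numeric(width)
  W2 <- matrix(r$norm(width, 0, sqrt(1 / width)), width, 1)
  b2 <- mean(y[tr])
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- 0
  set.seed(derive_seed(seed, 8009L))
  for (e in seq_len(epochs)) {
    ord <- sample(tr)
    for (ids in split(ord, ceiling(seq_along(ord) / batch))) {
      X <- feat[, ids, drop = FALSE]
      z1 <- crossprod(W1, X) + b1
      a1 <- pmax(z1, 0)
      dm <- NULL
      h1 <- a1
      if (dropout > 0) {
        dm <- matrix(stats::runif(length(a1)) >= dropout, nrow(a1), ncol(a1)) / (1 - dropout)
        h1 <- a1 * dm
      }
      pred <- as.numeric(crossprod(W2, h1)) + b2
      err <- pred - y[ids]
      dp <- 2 * err / length(err)
      gW2 <- h1 %*% dp
      gb2 <- sum(dp)
      dh1 <- W2 %*% matrix(dp, 1)
      if (!is.null(dm)) dh1 <- dh1 * dm
      dz1 <- dh1 * (z1 > 0)
      gW1 <- X %*% t(dz1)
      gb1 <- rowSums(dz1)
      vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
      vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
      vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
      vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
    }
  }
  z1 <- crossprod(W1, feat[, val_idx, drop = FALSE]) + b1
  pv <- as.numeric(crossprod(W2, pmax(z1, 0))) + b2
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
       val_rmse = rmse(pv, val_targets))
}

#' Retrain the FC4 head at a new width with a frozen prefix
#'
#' All weights before FC4 are kept bit-identical; a fresh FC4 of the given
#' width (plus dropout and output layer) is trained `repeats` times from
#' different initialisations, and the best run by validation RMSE on the
#' perceived labels is kept.
#'
#' @param model a trained `slowfusion` model.
#' @param clips clip source covering training and validation stimuli.
#' @param labels physical training labels.
#' @param val_ids validation indices.
#' @param val_perceived perceived targets for validation.
#' @param width new FC4 width.
#' @param repeats independent retraining runs (default 10).
#' @param epochs per-run epochs.
#' @param seed base seed.
#' @return the retrained model (same class, new head) with `head_rmses`
#'   (per-repeat validation RMSEs) attached.
#' @export
retrain_head <- function(model, clips, labels, val_ids, val_perceived = NULL,
                         width, repeats = 10, epochs = 30, seed = 1L) {
  if (width < 1) stop("config error: width must be >= 1")
  if (is.null(val_perceived)) val_perceived <- labels[val_ids]
  feat <- sf_prefix_features(model, clips)
  runs <- lapply(seq_len(repeats), function(rp) {
    train_fc_head(feat, labels, width, val_ids, val_perceived,
                  epochs = epochs, lr = 1e-3,
                  dropout = model$config$dropout, seed = derive_seed(seed, width, rp))
  })
  rmses <- vapply(runs, function(x) x$val_rmse, numeric(1))
  best <- runs[[which.min(rmses)]]
  out <- model
  out$config$fc4_width <- as.integer(width)
  out$params$W4 <- best$W1
  out$params$b4 <- best$b1
  out$params$W5 <- best$W2
  out$params$b5 <- best$b2
  out$head_rmses <- rmses
  out
}

#' Retrain the head for scene classification (transfer learning)
#'
#' Keeps all layers before FC4 frozen and retrains FC4 plus a softmax
#' output on scene-class labels for a few epochs (default 8). Reports
#' overall accuracy, mean one-vs-rest AUC and the class-probability matrix
#' on the held-out set.
#'
#' @param model a trained `slowfusion` model (possibly a compressed-head
#'   variant; its current FC4 width is reused).
#' @param clips clip source.
#' @param scene_labels integer scene class per clip.
#' @param val_ids held-out stimuli for evaluation.
#' @param epochs training epochs (default 8).
#' @param lr learning rate.
#' @param seed seed.
#' @return list with `accuracy`, `auc`, `prob_matrix` (class x class mean
#'   probabilities), `pred` and the trained head.
#' @export
retrain_scene_head <- function(model, clips, scene_labels, val_ids,
                               epochs = 8, lr = 2e-3, seed = 1L) {
  classes <- sort(unique(scene_labels))
  K <- length(classes)
  if (K < 2) stop("classification error: need at least two scene classes")
  y <- match(scene_labels, classes)
  feat <- sf_prefix_features(model, clips)
  d <- nrow(feat)
  width <- model$config$fc4_width
  n <- ncol(feat)
  tr <- setdiff(seq_len(n), val_ids)
  r <- rng_stream(derive_seed(seed, 8108L))
  W1 <- matrix(r$norm(d * width, 0, sqrt(2 / d)), d, width)
  b1 <- numeric(width)
  W2 <- matrix(r$norm(width * K, 0, sqrt(1 / width)), width, K)
  b2 <- numeric(K)
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
  mom <- 0.9
  set.seed(derive_seed(seed, 8110L))
  for (e in seq_len(epochs)) {
    ord <- sample(tr)
    for (ids in split(ord, ceiling(seq_along(ord) / 64))) {
      X <- feat[, ids, drop = FALSE]
      z1 <- crossprod(W1, X) + b1
      a1 <- pmax(z1, 0)
      sc <- crossprod(W2, a1) + b2 # K x B
      sc <- sweep(sc, 2, apply(sc, 2, max))
      P <- exp(sc)
      P <- sweep(P, 2, colSums(P), "/")
      Yh <- matrix(0, K, length(ids))
      Yh[cbind(y[ids], seq_along(ids))] <- 1
      dsc <- (P - Yh) / length(ids)
      gW2 <- a1 %*% t(dsc)
      gb2 <- rowSums(dsc)
      da1 <- W2 %*% dsc
      dz1 <- da1 * (z1 > 0)
      gW1 <- X %*% t(dz1)
      gb1 <- rowSums(dz1)
      vW1 <- mom * vW1 - lr * gW1; W1 <- W1 + vW1
      vb1 <- mom * vb1 - lr * gb1; b1 <- b1 + vb1
      vW2 <- mom * vW2 - lr * gW2; W2 <- W2 + vW2
      vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
    }
  }
  z1 <- crossprod(W1, feat[, val_ids, drop = FALSE]) + b1
  sc <- crossprod(W2, pmax(z1, 0)) + b2
  sc <- sweep(sc, 2, apply(sc, 2, max))
  P <- exp(sc)
  P <- sweep(P, 2, colSums(P), "/") # K x n_val
  pred <- classes[apply(P, 2, which.max)]
  truth <- scene_labels[val_ids]
  acc <- mean(pred == truth)
  aucs <- vapply(seq_len(K), function(k) {
    resp <- as.integer(truth == classes[k])
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, P[k, ], quiet = TRUE, direction = "<")))
  }, numeric(1))
  pm <- t(vapply(seq_len(K), function(k) {
    rowMeans(P[, truth == classes[k], drop = FALSE])
  }, numeric(K))) # true class x predicted class mean probability
  dimnames(pm) <- list(true = classes, predicted = classes)
  list(accuracy = acc, auc = mean(aucs, na.rm = TRUE), prob_matrix = pm,
       pred = pred, head = list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                                classes = classes))
}
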