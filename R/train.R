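# Training, prediction, activation capture and lesioning.

#' Desk-scale slow-fusion configuration
#'
#' A reduced preset with the same temporal geometry as the default
#' architecture (8/12/20-frame pathways at stride 4) but far fewer filters,
#' smaller kernels, an extra input downsampling step and a narrow FC4, sized
#' so that a ~2,000-clip study trains in minutes on one CPU. The optimiser
#' settings are re-tuned for this scale.
#'
#' @param ... overrides passed to [slowfusion_config()].
#' @return a `slowfusion_config`.
#' @export
slowfusion_config_small <- function(...) {
  args <- list(
    conv_channels = c(8L, 16L, 16L),
    kernel = c(3L, 3L, 3L),
    conv_stride = c(2L, 1L, 1L),
    input_pool = 2L,
    fc4_width = 64L,
    dropout = 0.2,
    learning_rate = 2e-3,
    momentum = 0.9,
    l2 = 1e-5,
    batch_size = 32L
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(slowfusion_config, args)
}

# Resolve a clips argument (clipset / movie_clip / list of clips) to a
# function pulling pixel-matrix batches, plus the count.
clips_source <- function(clips) {
  if (inherits(clips, "clipset")) {
    list(n = length(clips), get = function(idx) clipset_batch(clips, idx))
  } else if (inherits(clips, "movie_clip")) {
    m <- matrix(as.numeric(clips), ncol = 1)
    list(n = 1L, get = function(idx) m[, idx, drop = FALSE])
  } else if (is.list(clips)) {
    list(n = length(clips), get = function(idx) {
      vapply(idx, function(i) as.numeric(clips[[i]]), numeric(prod(CLIP_DIM)))
    })
  } else {
    stop("input error: clips must be a clipset, movie_clip, or list of clips")
  }
}

# Replace colour by Rec.709 luminance replicated over the three channels.
grayscale_batch <- function(X) {
  n <- ncol(X)
  a <- array(X, c(prod(CLIP_DIM[1:3]), 3, n))
  y <- a[, 1, ] * 0.2126 + a[, 2, ] * 0.7152 + a[, 3, ] * 0.0722
  a[, 1, ] <- y
  a[, 2, ] <- y
  a[, 3, ] <- y
  dim(a) <- dim(X)
  a
}

#' Train a slow-fusion network
#'
#' Stochastic gradient descent with momentum and L2 regularisation on the
#' mean squared error between predicted and physical viscosity labels (on the
#' linear 1..16 scale). Per epoch, the history records the running training
#' RMSE (mean of the last ten batches), the validation RMSE on physical
#' labels, and the validation RMSE on perceived labels.
#'
#' @param model a `slowfusion` model from [build_network()].
#' @param clips a `clipset` (or list of clips) covering training and
#'   validation stimuli.
#' @param labels physical viscosity step per clip (1..16 scale).
#' @param val_ids clip indices held out for validation (disjoint from
#'   training; if `NULL`, a per-scene fraction `holdout_frac` is withheld).
#' @param val_perceived perceived-viscosity targets for the validation clips
#'   (defaults to the physical labels).
#' @param exclude_scene scene class(es) excluded entirely from the training
#'   set, for generalisation testing.
#' @param holdout_frac per-scene withheld fraction used when `val_ids` is
#'   `NULL` (default 0.008).
#' @param epochs training epochs (default from the config).
#' @param seed seed controlling shuffling and dropout.
#' @param verbose print per-epoch errors.
#' @return the trained model, with a `history` data frame attached.
#' @export
sf_train <- function(model, clips, labels, val_ids = NULL,
                     val_perceived = NULL, exclude_scene = NULL,
                     holdout_frac = 0.008, epochs = model$config$epochs,
                     seed = 1L, verbose = FALSE) {
  if (inherits(clips, "clipset") && model$config$input_pool > 1 &&
      is.null(clips$pooled)) {
    clips <- sf_downsample_clipset(clips, model$config)
  }
  src <- clips_source(clips)
  stopifnot(length(labels) == src$n)
  if (any(labels < 1 | labels > 16)) stop("labels must lie on the 1..16 scale")
  design <- if (inherits(clips, "clipset")) clips$design else NULL

  all_ids <- seq_len(src$n)
  if (is.null(val_ids)) {
    if (!is.null(design)) {
      val_ids <- unlist(lapply(split(all_ids, design$scene_class), function(ii) {
        k <- max(1L, round(length(ii) * holdout_frac))
        ii[seq_len(k)]
      }), use.names = FALSE)
    } else {
      val_ids <- all_ids[seq_len(max(1L, round(src$n * holdout_frac)))]
    }
  }
  train_ids <- setdiff(all_ids, val_ids)
  if (!is.null(exclude_scene) && !is.null(design)) {
    train_ids <- train_ids[!design$scene_class[train_ids] %in% exclude_scene]
  }
  if (!length(train_ids)) stop("empty training set")
  if (is.null(val_perceived)) val_perceived <- labels[val_ids]
  stopifnot(length(val_perceived) == length(val_ids))

  cfg <- model$config
  # centre inputs on the training-set mean pixel
  probe <- src$get(train_ids[seq_len(min(50, length(train_ids)))])
  model$mean_pixel <- mean(probe)

  vel <- lapply(model$params, function(w) w * 0)
  lr <- cfg$learning_rate
  mom <- cfg$momentum
  l2 <- cfg$l2
  bs <- cfg$batch_size
  hist <- data.frame(epoch = integer(0), train_rmse = numeric(0),
                     val_phys_rmse = numeric(0), val_perc_rmse = numeric(0))
  set.seed(derive_seed(seed, 77L))
  for (ep in seq_len(epochs)) {
    ord <- sample(train_ids)
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    bloss <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      X <- src$get(idx)
      y <- labels[idx]
      fw <- sf_forward(model, X, train = TRUE, keep = TRUE)
      err <- fw$pred - y
      bloss[bi] <- sqrt(mean(err^2))
      dpred <- 2 * err / length(err)
      gr <- sf_backward(model, fw, dpred)
      for (nm in names(model$params)) {
        g <- gr[[nm]] + l2 * model$params[[nm]]
        vel[[nm]] <- mom * vel[[nm]] - lr * g
        model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
      }
    }
    vp <- sf_predict_ids(model, src, val_ids)
    tr_rmse <- mean(utils::tail(bloss, 10))
    row <- data.frame(
      epoch = ep, train_rmse = tr_rmse,
      val_phys_rmse = if (length(val_ids)) rmse(vp, labels[val_ids]) else NA_real_,
      val_perc_rmse = if (length(val_ids)) rmse(vp, val_perceived) else NA_real_
    )
    hist <- rbind(hist, row)
    if (verbose) {
      cat(sprintf("epoch %2d  train %.3f  val phys %.3f  val perc %.3f\n",
                  ep, row$train_rmse, row$val_phys_rmse, row$val_perc_rmse))
    }
  }
  model$history <- hist
  model$train_ids <- train_ids
  model$val_ids <- val_ids
  model
}

sf_predict_ids <- function(model, src, ids, batch = 64L, transform = "none") {
  out <- numeric(length(ids))
  for (ch in split(seq_along(ids), ceiling(seq_along(ids) / batch))) {
    X <- src$get(ids[ch])
    if (transform == "grayscale") X <- grayscale_batch(X)
    out[ch] <- sf_forward(model, X)$pred
  }
  out
}

#' Predict viscosity for clips
#'
#' @param object a `slowfusion` model.
#' @param clips a `clipset`, a single `movie_clip`, or a list of clips.
#' @param transform optional input transform: `"none"` or `"grayscale"`
#'   (replaces the channels by their luminance, replicated).
#' @param ... unused.
#' @return one finite viscosity estimate per clip (1..16 scale units).
#' @export
predict.slowfusion <- function(object, clips, transform = c("none", "grayscale"),
                               ...) {
  transform <- match.arg(transform)
  src <- clips_source(clips)
  sf_predict_ids(object, src, seq_len(src$n), transform = transform)
}

#' Capture ReLU activations for a set of clips
#'
#' Conv-unit responses are the flattened post-ReLU activation maps of the
#' unit's filter concatenated across parallel pathways; FC4 responses are
#' scalars. Units that never activate over the probe set are flagged dead.
#'
#' @param model a `slowfusion` model.
#' @param clips clip source.
#' @param layer `"relu1"`, `"relu2"`, `"relu3"` or `"relu4"`.
#' @param batch forward batch size.
#' @return an `activation_record`: list with `layer`, `resp` (stimuli x
#'   features), `units` (feature column -> unit id map), `pooled` (stimuli x
#'   units, summed rectified maps) and `dead` (logical per unit).
#' @export
collect_activations <- function(model, clips, layer = c("relu1", "relu2", "relu3", "relu4"),
                                batch = 64L) {
  layer <- match.arg(layer)
  src <- clips_source(clips)
  cfg <- model$config
  li <- as.integer(substring(layer, 5))
  out <- NULL
  for (ch in split(seq_len(src$n), ceiling(seq_len(src$n) / batch))) {
    X <- src$get(ch)
    fw <- sf_forward(model, X, want_acts = TRUE)
    A <- fw[[layer]] # (rows, P*B) conv or (F, B) fc
    if (li <= 3) {
      P <- cfg$n_pathways[li]
      B <- length(ch)
      # (h*w*C, P, B) -> stimuli rows, unit-major columns: (P*h*w per unit)
      a <- array(A, c(nrow(A), P, B))
      a <- aperm(a, c(3, 1, 2)) # (B, h*w*C, P)
      dim(a) <- c(B, nrow(A) * P)
      # columns currently ordered (pos within unit, unit, pathway);
      # regroup to unit-major: (pos, pathway) within unit
      hw <- nrow(A) / cfg$conv_channels[li]
      perm <- as.vector(outer(
        outer(seq_len(hw), (seq_len(P) - 1) * nrow(A), "+"),
        (seq_len(cfg$conv_channels[li]) - 1) * hw, "+"
      ))
      a <- a[, perm, drop = FALSE]
    } else {
      a <- t(A)
    }
    out <- rbind(out, a)
  }
  if (li <= 3) {
    C <- cfg$conv_channels[li]
    per <- ncol(out) / C
    units_global <- model$registry$unit[model$registry$layer == li]
    unit_of_col <- rep(units_global, each = per)
    pooled <- out %*% Matrix::sparseMatrix(
      i = seq_len(ncol(out)), j = rep(seq_len(C), each = per), x = 1,
      dims = c(ncol(out), C)
    )
    pooled <- as.matrix(pooled)
    colnames(pooled) <- units_global
    dead <- colSums(abs(pooled)) == 0
  } else {
    unit_of_col <- seq_len(ncol(out))
    pooled <- out
    dead <- colSums(abs(out)) == 0
  }
  structure(
    list(layer = layer, resp = out, unit_of_col = unit_of_col,
         units = unique(unit_of_col), pooled = pooled, dead = dead),
    class = "activation_record"
  )
}

#' @export
print.activation_record <- function(x, ...) {
  cat(sprintf("Activations at %s: %d stimuli x %d features (%d units, %d dead)\n",
              x$layer, nrow(x$resp), ncol(x$resp), length(x$units), sum(x$dead)))
  invisible(x)
}

#' Lesion a set of units
#'
#' Returns a copy of the model in which the listed conv units' ReLU outputs
#' are clamped to zero for every input; the original model is unmodified.
#' Lesions compose: lesioning A then B equals lesioning the union.
#'
#' @param model a `slowfusion` model.
#' @param units global conv-unit ids (see `model$registry`).
#' @return the lesioned model.
#' @export
lesion_units <- function(model, units) {
  units <- as.integer(units)
  if (length(units) && !all(units %in% model$registry$unit)) {
    stop("registry error: unknown unit id(s): ",
         paste(setdiff(units, model$registry$unit), collapse = ", "))
  }
  model$lesion <- sort(unique(c(model$lesion, units)))
  model
}
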