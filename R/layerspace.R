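# Layer-level analyses ("virtual fMRI"): layer RSA profiles, per-layer
# decoding curves, the FC4 capacity experiment, scene-transfer comparison,
# and stimulus-space embeddings.

#' Layer RSA profile
#'
#' The layer's activation vectors (all unit responses concatenated) are
#' turned into a one-minus-Pearson RDM and rank-correlated with each
#' predictor RDM. Two-sided significance comes from permuting stimulus
#' labels of the layer RDM.
#'
#' @param act an `activation_record` for one layer.
#' @param rdms predictor `rdm`s built with the layer-level convention.
#' @param n_perm label permutations for significance (default 1000).
#' @param seed permutation seed.
#' @return a data frame with `predictor`, `rho`, `p`.
#' @export
layer_profile <- function(act, rdms, n_perm = 1000, seed = 1L) {
  lr <- rdm_from_features(act$resp, "one_minus_pearson")
  n <- nrow(lr)
  obs <- vapply(rdms, function(p) compare_rdms(lr, p)$rho, numeric(1))
  r <- rng_stream(derive_seed(seed, 3003L))
  exceed <- numeric(length(rdms))
  M <- unclass(lr)
  for (b in seq_len(n_perm)) {
    pidx <- order(r$unif(n))
    Mp <- M[pidx, pidx]
    rho_p <- vapply(rdms, function(p) compare_rdms(Mp, p)$rho, numeric(1))
    exceed <- exceed + (abs(rho_p) >= abs(obs))
  }
  data.frame(
    predictor = names(rdms),
    rho = unname(obs),
    p = if (n_perm > 0) unname((exceed + 1) / (n_perm + 1)) else NA_real_,
    row.names = NULL
  )
}

#' Per-layer linear decoding curve
#'
#' Fits [fit_linear_decoder()] on each ReLU layer's activations and reports
#' held-out RMSE per layer, alongside the full network's RMSE on the same
#' held-out stimuli.
#'
#' @param model a trained `slowfusion`.
#' @param clips clip source.
#' @param targets perceived-viscosity targets.
#' @param layers layer tags.
#' @param seed split seed (shared across layers).
#' @param epochs decoder training steps.
#' @return data frame with `layer`, `rmse`, plus the network reference RMSE
#'   as attribute `network_rmse`.
#' @export
decoder_curve <- function(model, clips, targets,
                          layers = c("relu1", "relu2", "relu3", "relu4"),
                          seed = 1L, epochs = 300) {
  out <- data.frame(layer = layers, rmse = NA_real_)
  dec1 <- NULL
  for (i in seq_along(layers)) {
    act <- collect_activations(model, clips, layers[i])
    dec <- fit_linear_decoder(act$resp, targets, seed = seed, epochs = epochs)
    out$rmse[i] <- dec$rmse
    if (is.null(dec1)) dec1 <- dec
  }
  preds <- predict(model, clips)
  attr(out, "network_rmse") <- rmse(preds[dec1$test], targets[dec1$test])
  out
}

#' FC4 capacity-compression experiment
#'
#' Retrains the FC4 head at each width in the grid (frozen prefix),
#' `repeats` times per width, keeping the best run per width by validation
#' RMSE on perceived labels.
#'
#' @param model trained `slowfusion`.
#' @param clips clip source.
#' @param labels physical labels.
#' @param val_ids validation indices.
#' @param val_perceived perceived validation targets.
#' @param widths width grid (default spans the full head down to 1 unit).
#' @param repeats runs per width (default 10).
#' @param epochs per-run epochs.
#' @param seed base seed.
#' @return a `capacity_curve`: data frame with `width`, `best_rmse`,
#'   `mean_rmse`, `sd_rmse`; the best compressed model (default reference
#'   width 15) attached as attribute `reference_model`.
#' @export
capacity_experiment <- function(model, clips, labels, val_ids,
                                val_perceived = NULL,
                                widths = c(model$config$fc4_width, 256, 64, 15, 4, 1),
                                repeats = 10, epochs = 30, seed = 1L) {
  widths <- sort(unique(pmax(1, as.integer(widths))), decreasing = TRUE)
  if (is.null(val_perceived)) val_perceived <- labels[val_ids]
  feat <- sf_prefix_features(model, clips)
  res <- data.frame(width = widths, best_rmse = NA_real_,
                    mean_rmse = NA_real_, sd_rmse = NA_real_)
  ref_model <- NULL
  ref_width <- if (15 %in% widths) 15L else widths[which.min(abs(widths - 15))]
  for (i in seq_along(widths)) {
    w <- widths[i]
    runs <- lapply(seq_len(repeats), function(rp) {
      train_fc_head(feat, labels, w, val_ids, val_perceived,
                    epochs = epochs, dropout = model$config$dropout,
                    seed = derive_seed(seed, w, rp))
    })
    rm_ <- vapply(runs, function(x) x$val_rmse, numeric(1))
    res$best_rmse[i] <- min(rm_)
    res$mean_rmse[i] <- mean(rm_)
    res$sd_rmse[i] <- stats::sd(rm_)
    if (w == ref_width) {
      best <- runs[[which.min(rm_)]]
      ref_model <- model
      ref_model$config$fc4_width <- w
      ref_model$params$W4 <- best$W1
      ref_model$params$b4 <- best$b1
      ref_model$params$W5 <- best$W2
      ref_model$params$b5 <- best$b2
    }
  }
  attr(res, "reference_model") <- ref_model
  class(res) <- c("capacity_curve", "data.frame")
  res
}

#' @export
print.capacity_curve <- function(x, ...) {
  cat("FC4 capacity curve (best-of-repeats validation RMSE):\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' Scene-transfer comparison across head variants
#'
#' Runs [retrain_scene_head()] for each model variant (e.g. the full-width
#' head and the compressed reference head) and reports accuracy and AUC.
#'
#' @param models named list of `slowfusion` variants.
#' @param clips clip source.
#' @param scene_labels integer scene class per clip.
#' @param val_ids evaluation stimuli.
#' @param epochs transfer epochs (default 8).
#' @param seed seed.
#' @return data frame with `variant`, `accuracy`, `auc`; per-variant
#'   probability matrices in attribute `prob_matrices`.
#' @export
scene_transfer_compare <- function(models, clips, scene_labels, val_ids,
                                   epochs = 8, seed = 1L) {
  res <- data.frame(variant = names(models), accuracy = NA_real_, auc = NA_real_)
  pms <- list()
  for (i in seq_along(models)) {
    tr <- retrain_scene_head(models[[i]], clips, scene_labels, val_ids,
                             epochs = epochs, seed = seed)
    res$accuracy[i] <- tr$accuracy
    res$auc[i] <- tr$auc
    pms[[names(models)[i]]] <- tr$prob_matrix
  }
  attr(res, "prob_matrices") <- pms
  res
}

#' 2-D embedding of stimuli in a layer's activation space
#'
#' t-SNE layout of per-stimulus activation vectors at the given layer,
#' optionally jointly with the controlled reference clip set.
#'
#' @param model trained `slowfusion`.
#' @param clips clip source.
#' @param layer layer tag.
#' @param reference optional reference `clipset` embedded jointly.
#' @param seed layout seed.
#' @param ... passed to [tsne_embed()].
#' @return list with `coords` (n x 2), `is_reference` flag per row.
#' @export
stimulus_embedding <- function(model, clips, layer = "relu4",
                               reference = NULL, seed = 1L, ...) {
  act <- collect_activations(model, clips, layer)
  X <- act$resp
  is_ref <- rep(FALSE, nrow(X))
  if (!is.null(reference)) {
    ar <- collect_activations(model, reference, layer)
    X <- rbind(X, ar$resp)
    is_ref <- c(is_ref, rep(TRUE, nrow(ar$resp)))
  }
  list(coords = tsne_embed(X, seed = seed, ...), is_reference = is_ref)
}
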