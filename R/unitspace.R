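# Unit-level analyses ("virtual electrophysiology"): embedding units in the
# 18-predictor correlation space, kNN-Louvain clustering, cluster centres,
# extreme stimuli, lesion tests against size-matched nulls, and activation
# maximization.

#' Embed units in predictor space
#'
#' For each conv unit, builds the unit's Euclidean RDM over the stimulus set
#' from its full response map and rank-correlates it with each predictor
#' RDM, giving one 18-vector tuning profile per unit.
#'
#' @param acts list of `activation_record`s (one per conv layer, from
#'   [collect_activations()]).
#' @param rdms named list of predictor `rdm`s (unit-level convention).
#' @return a `unit_profiles` object: matrix units x predictors, with unit
#'   and layer ids as attributes.
#' @export
build_predictor_space <- function(acts, rdms) {
  if (!length(rdms)) stop("registry error: no predictor RDMs")
  # rank the predictor upper triangles once
  pred_rank <- vapply(rdms, function(r) rank(upper_tri_vec(unclass(r))),
                      numeric(length(upper_tri_vec(unclass(rdms[[1]])))))
  units <- integer(0)
  layers <- integer(0)
  prof <- NULL
  for (ar in acts) {
    li <- as.integer(substring(ar$layer, 5))
    for (u in ar$units) {
      cols <- which(ar$unit_of_col == u)
      rd <- rdm_from_features(ar$resp[, cols, drop = FALSE], "euclidean")
      ur <- rank(upper_tri_vec(unclass(rd)))
      prof <- rbind(prof, suppressWarnings(stats::cor(ur, pred_rank)))
      units <- c(units, u)
      layers <- c(layers, li)
    }
  }
  prof[!is.finite(prof)] <- 0
  dimnames(prof) <- list(NULL, names(rdms))
  structure(prof, unit = units, layer = layers, class = c("unit_profiles", "matrix"))
}

#' @export
print.unit_profiles <- function(x, ...) {
  cat(sprintf("Unit profiles: %d units x %d predictors\n", nrow(x), ncol(x)))
  invisible(x)
}

# kNN graph in profile space with inverse-distance similarity weights.
knn_graph <- function(profiles, k) {
  n <- nrow(profiles)
  if (n <= k) stop("graph error: need more units than neighbours")
  sq <- rowSums(profiles^2)
  D <- sqrt(pmax(outer(sq, sq, "+") - 2 * tcrossprod(profiles), 0))
  edges <- NULL
  wts <- NULL
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1)]
    edges <- rbind(edges, cbind(i, nb))
    wts <- c(wts, 1 / (1 + D[i, nb]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- wts
  g <- igraph::simplify(g, edge.attr.comb = "max")
  g
}

#' Cluster unit profiles with kNN-Louvain
#'
#' Builds a k-nearest-neighbour graph in the full predictor space (Euclidean
#' distances; inverse-distance similarity weights in (0, 1]) and runs
#' Louvain community detection. The default k is the square root of the
#' number of units, rounded (k = 20 for 420 units).
#'
#' @param profiles a `unit_profiles` matrix.
#' @param k neighbours (default `round(sqrt(n_units))`).
#' @param seed seed for the Louvain pass.
#' @return a `cluster_assignment`: list with `membership` (per unit),
#'   `k`, `centres` (per-cluster centre unit index) and the graph.
#' @export
cluster_units <- function(profiles, k = round(sqrt(nrow(profiles))), seed = 1L) {
  g <- knn_graph(unclass(profiles), k)
  r <- rng_stream(derive_seed(seed, 1201L))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(derive_seed(seed, 1202L))
  cl <- igraph::cluster_louvain(g)
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  memb <- igraph::membership(cl)
  out <- list(membership = as.integer(memb), k = k, graph = g,
              units = attr(profiles, "unit"), layers = attr(profiles, "layer"))
  out$centres <- cluster_centre(profiles, out)
  class(out) <- "cluster_assignment"
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Louvain clustering: %d units, k = %d, %d communities\n",
              length(x$membership), x$k, length(unique(x$membership))))
  invisible(x)
}

#' Centre unit of each cluster
#'
#' The member with the largest mean graph weight to its co-members (absent
#' edges count as weight zero); ties broken by the lowest unit index.
#'
#' @param profiles the `unit_profiles` used for clustering.
#' @param assignment a `cluster_assignment` (or list with `membership` and
#'   `graph`).
#' @return named integer vector: centre unit row index per cluster id.
#' @export
cluster_centre <- function(profiles, assignment) {
  memb <- assignment$membership
  W <- igraph::as_adjacency_matrix(assignment$graph, attr = "weight", sparse = FALSE)
  vapply(sort(unique(memb)), function(cl) {
    ii <- which(memb == cl)
    if (length(ii) == 1) return(ii)
    mw <- rowMeans(W[ii, ii, drop = FALSE])
    ii[which.max(mw)] # which.max takes the first (lowest index) on ties
  }, integer(1))
}

#' Stimuli minimising and maximising a unit's response
#'
#' Responses are pooled to one scalar per stimulus (sum of the rectified
#' map by default).
#'
#' @param act an `activation_record`.
#' @param unit unit id within the record.
#' @param pool `"sum"`, `"mean"` or `"max"`.
#' @return list with `min`, `max` (stimulus indices) and `degenerate`
#'   (TRUE when all pooled responses are equal).
#' @export
minmax_stimuli <- function(act, unit, pool = c("sum", "mean", "max")) {
  pool <- match.arg(pool)
  cols <- which(act$unit_of_col == unit)
  if (!length(cols)) stop("registry error: unknown unit ", unit)
  r <- act$resp[, cols, drop = FALSE]
  v <- switch(pool,
    sum = rowSums(r),
    mean = rowMeans(r),
    max = apply(r, 1, max)
  )
  list(min = which.min(v), max = which.max(v),
       degenerate = diff(range(v)) == 0)
}

#' Lesion a unit set and compare against size-matched random lesions
#'
#' Measures the change in prediction RMSE caused by lesioning the given
#' units, against a null distribution of equally sized uniformly drawn unit
#' sets, and reports the z-score.
#'
#' @param model a `slowfusion` model.
#' @param units conv-unit ids to lesion.
#' @param clips evaluation clip source.
#' @param targets evaluation targets (perceived or physical labels).
#' @param n_null null draws (default 1000).
#' @param seed seed for the null draws.
#' @return a `lesion_result`: list with `delta` (RMSE change), `null`
#'   (vector of null deltas), `z`.
#' @export
lesion_test <- function(model, units, clips, targets, n_null = 1000, seed = 1L) {
  src <- clips_source(clips)
  base <- rmse(sf_predict_ids(model, src, seq_len(src$n)), targets)
  delta <- rmse(sf_predict_ids(lesion_units(model, units), src, seq_len(src$n)),
                targets) - base
  all_units <- model$registry$unit
  r <- rng_stream(derive_seed(seed, 5005L))
  nulls <- numeric(n_null)
  for (b in seq_len(n_null)) {
    draw <- all_units[r$int(length(units), length(all_units))]
    # sample without replacement via rejection-free reservoir: re-draw dupes
    draw <- unique(draw)
    while (length(draw) < length(units)) {
      draw <- unique(c(draw, all_units[r$int(length(units) - length(draw),
                                             length(all_units))]))
    }
    nulls[b] <- rmse(sf_predict_ids(lesion_units(model, draw), src, seq_len(src$n)),
                     targets) - base
  }
  sdn <- stats::sd(nulls)
  if (sdn == 0) stop("undefined z: null distribution has zero spread")
  structure(list(delta = delta, null = nulls, z = (delta - mean(nulls)) / sdn),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat(sprintf("Lesion: delta RMSE %.4f, null mean %.4f (sd %.4f), z = %.2f\n",
              x$delta, mean(x$null), stats::sd(x$null), x$z))
  invisible(x)
}

#' Activation maximization
#'
#' Gradient ascent on the input clip maximising a unit's pooled (summed
#' rectified) response, starting from the dataset mean clip plus Gaussian
#' white noise. Keeps the best input seen, so the final activation is never
#' below the seed's.
#'
#' @param model a `slowfusion` model.
#' @param unit conv-unit id (or `list(layer = 4, unit = i)` for FC4 units).
#' @param mean_clip dataset mean clip (numeric vector or `movie_clip`);
#'   defaults to a uniform 0.5 clip.
#' @param iterations gradient steps (default 2000).
#' @param pyramid_levels reserved; one level supported.
#' @param lr ascent step size.
#' @param noise_sd seed-image noise level.
#' @param seed RNG seed.
#' @return list with `clip` (optimised input), `trace` (activation per
#'   iteration), `dead` (TRUE when the unit never responded to the seed and
#'   the seed is returned).
#' @export
activation_maximize <- function(model, unit, mean_clip = NULL,
                                iterations = 2000, pyramid_levels = 1,
                                lr = 0.05, noise_sd = 0.05, seed = 1L) {
  if (is.list(unit)) {
    layer <- unit$layer
    uidx <- unit$unit
  } else {
    if (!unit %in% model$registry$unit) stop("registry error: unknown unit ", unit)
    layer <- model$registry$layer[model$registry$unit == unit]
    uidx <- model$registry$channel[model$registry$unit == unit]
  }
  r <- rng_stream(derive_seed(seed, 6006L))
  x0 <- if (is.null(mean_clip)) rep(0.5, prod(CLIP_DIM)) else as.numeric(mean_clip)
  x <- clamp(x0 + r$norm(length(x0), 0, noise_sd), 0, 1)
  X <- matrix(x, ncol = 1)
  trace <- numeric(iterations)
  best <- X
  best_act <- -Inf
  for (it in seq_len(iterations)) {
    fb <- sf_unit_gradient(model, X, layer, uidx)
    trace[it] <- fb$act
    if (fb$act >= best_act) {
      best_act <- fb$act
      best <- X
    }
    if (all(fb$grad == 0)) {
      if (it == 1) {
        return(list(clip = structure(array(X, CLIP_DIM), class = "movie_clip"),
                    trace = trace[1], dead = TRUE))
      }
      break
    }
    g <- fb$grad / max(sqrt(mean(fb$grad^2)), 1e-12)
    X <- clamp(X + lr * g, 0, 1)
  }
  list(clip = structure(array(best, CLIP_DIM), class = "movie_clip"),
       trace = trace[seq_len(it)], dead = FALSE)
}

# Activation of one unit's pooled ReLU response and its gradient wrt the
# input clip.
sf_unit_gradient <- function(model, X, layer, channel) {
  cfg <- model$config
  geo <- model$geom
  p <- model$params
  fw <- sf_forward(model, X, keep = TRUE)
  g1 <- geo$g[[1]]; g2 <- geo$g[[2]]; g3 <- geo$g[[3]]
  share <- cfg$share_pathway_filters
  zl <- list(fw$c1$out, fw$c2$out, fw$c3$out)
  if (layer == 4) {
    act <- sum(pmax(fw$z4[channel, ], 0))
    dz4 <- matrix(0, nrow(fw$z4), ncol(fw$z4))
    dz4[channel, ] <- (fw$z4[channel, ] > 0)
    dfeat <- p$W4 %*% dz4
    da3 <- pool_backward(dfeat, fw$p3)
    dz <- da3 * (fw$c3$out > 0)
    from <- 3
  } else {
    gg <- list(g1, g2, g3)[[layer]]
    rows <- ((channel - 1) * gg$P + 1):(channel * gg$P)
    z <- zl[[layer]]
    act <- sum(pmax(z[rows, ], 0))
    dz <- matrix(0, nrow(z), ncol(z))
    dz[rows, ] <- (z[rows, ] > 0)
    from <- layer
  }
  # backprop from stage `from` pre-activation gradient down to the input
  if (from == 3) {
    bk3 <- conv_backward(dz, p$W3, g3, fw$c3, TRUE)
    dp2 <- matrix(0, nrow(fw$p2$out), ncol(fw$p2$out))
    rows_per <- nrow(fw$p2$out)
    for (q in seq_along(fw$fu3)) {
      dp2[, fw$fu3[[q]]] <- bk3$dx[((q - 1) * rows_per + 1):(q * rows_per), , drop = FALSE]
    }
    dz <- pool_backward(dp2, fw$p2) * (fw$c2$out > 0)
    from <- 2
  }
  if (from == 2) {
    bk2 <- stage_conv_backward(dz, p$W2, g2, fw$c2, cfg$n_pathways[2], share)
    dp1 <- matrix(0, nrow(fw$p1$out), ncol(fw$p1$out))
    half <- nrow(fw$p1$out)
    dp1[, fw$fu2[[1]]] <- bk2$dx[1:half, , drop = FALSE]
    dp1[, fw$fu2[[2]]] <- dp1[, fw$fu2[[2]], drop = FALSE] +
      bk2$dx[(half + 1):(2 * half), , drop = FALSE]
    dz <- pool_backward(dp1, fw$p1) * (fw$c1$out > 0)
  }
  bk1 <- stage_conv_backward(dz, p$W1, g1, fw$c1, cfg$n_pathways[1], share)
  # scatter pathway-input gradient back onto the (downsampled) clip pixels
  dx1 <- bk1$dx # (D1, P1*B)
  B <- fw$B
  P1 <- cfg$n_pathways[1]
  D1 <- nrow(dx1)
  dim(dx1) <- c(D1 * P1, B)
  if (is.null(model$input_scatter)) {
    pidx <- as.vector(model$path_idx)
    model$input_scatter <- Matrix::sparseMatrix(
      i = pidx, j = seq_along(pidx), x = 1,
      dims = c(cfg$frames * geo$h0 * geo$w0 * cfg$channels, length(pidx))
    )
  }
  dXd <- as.matrix(model$input_scatter %*% dx1)
  ip <- cfg$input_pool
  if (ip > 1) {
    # each full-res pixel contributed 1/ip^2 to its pooled pixel
    a <- array(0, c(cfg$frames, cfg$height, cfg$width, cfg$channels * B))
    dd <- array(dXd, c(cfg$frames, geo$h0, geo$w0, cfg$channels * B))
    for (dy in seq_len(ip)) {
      for (dx_ in seq_len(ip)) {
        a[, seq(dy, by = ip, length.out = geo$h0),
          seq(dx_, by = ip, length.out = geo$w0), ] <- dd / (ip * ip)
      }
    }
    dX <- matrix(a, ncol = B)
  } else {
    dX <- dXd
  }
  list(act = act, grad = dX)
}

#' 2-D embedding of unit profiles
#'
#' t-SNE layout of the tuning profiles, for visualization only (clustering
#' always runs in the full predictor space).
#'
#' @param profiles a `unit_profiles` matrix.
#' @param seed layout seed.
#' @param ... passed to [tsne_embed()].
#' @return n x 2 coordinates.
#' @export
embed_2d <- function(profiles, seed = 1L, ...) {
  tsne_embed(unclass(profiles), seed = seed, ...)
}
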