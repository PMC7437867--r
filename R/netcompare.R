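# Network-level comparisons ("virtual individual differences") and the
# behavioural statistics suite: linear CKA, multi-seed training populations,
# the network-clustering check, human-vs-network comparison statistics and
# the bootstrap rating baseline.

#' Linear centered kernel alignment
#'
#' Similarity between two activation matrices over the same stimuli.
#' Columns are centred by subtracting the mean across observations
#' (cocktail-blank normalisation); the similarity is the squared Frobenius
#' norm of the cross-covariance normalised by the within-covariance norms.
#' Invariant to orthogonal transforms and isotropic scaling of either
#' feature space; lies in `[0, 1]`.
#'
#' @param a,b stimuli x features matrices (widths may differ).
#' @return similarity in `[0, 1]`.
#' @export
linear_cka <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("alignment error: different stimulus counts")
  if (nrow(a) < 2) stop("need at least 2 stimuli")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  cross <- sum(crossprod(ac, bc)^2)
  na <- sqrt(sum(crossprod(ac)^2))
  nb <- sqrt(sum(crossprod(bc)^2))
  if (na == 0 || nb == 0) stop("undefined similarity: all-zero activations after centring")
  cross / (na * nb)
}

#' Train a population of networks and compare them with CKA
#'
#' Trains `n_networks` instances of one architecture on identical data with
#' different initial weights and shuffling, then computes per-layer pairwise
#' linear CKA over a probe stimulus set. The representative network is the
#' one with the lowest validation RMSE against the perceived targets.
#'
#' @param n_networks population size (>= 2).
#' @param config a `slowfusion_config`.
#' @param clips training clip source.
#' @param labels physical labels.
#' @param val_ids validation indices.
#' @param val_perceived perceived targets for validation and selection.
#' @param probe_ids stimuli used for activation probes (default the
#'   validation set).
#' @param epochs training epochs per network.
#' @param base_seed seed; network i uses seeds derived from it.
#' @param layers ReLU layers to compare.
#' @return a `cka_population`: list with `models`, `cka` (per-layer pairwise
#'   matrices), `summary` (mean and 1st/99th percentile per layer),
#'   `representative` (index), `val_rmse` per network.
#' @export
population_train <- function(n_networks, config, clips, labels, val_ids,
                             val_perceived = NULL, probe_ids = val_ids,
                             epochs = config$epochs, base_seed = 1L,
                             layers = c("relu1", "relu2", "relu3", "relu4")) {
  if (n_networks < 2) stop("need at least 2 networks")
  if (is.null(val_perceived)) val_perceived <- labels[val_ids]
  models <- vector("list", n_networks)
  val_rmse <- numeric(n_networks)
  for (i in seq_len(n_networks)) {
    m <- build_network(config, seed = derive_seed(base_seed, 11L, i))
    m <- sf_train(m, clips, labels, val_ids = val_ids,
                  val_perceived = val_perceived, epochs = epochs,
                  seed = derive_seed(base_seed, 13L, i))
    models[[i]] <- m
    val_rmse[i] <- utils::tail(m$history$val_perc_rmse, 1)
  }
  probe <- if (inherits(clips, "clipset")) {
    structure(list(data = clips$data[, probe_ids, drop = FALSE],
                   design = clips$design[probe_ids, , drop = FALSE],
                   pooled = clips$pooled), class = "clipset")
  } else {
    stop("population_train expects a clipset")
  }
  acts <- lapply(models, function(m) {
    lapply(layers, function(l) collect_activations(m, probe, l)$resp)
  })
  cka <- lapply(seq_along(layers), function(li) {
    M <- diag(1, n_networks)
    for (i in seq_len(n_networks)) {
      for (j in seq_len(n_networks)) {
        if (j <= i) next
        M[i, j] <- M[j, i] <- linear_cka(acts[[i]][[li]], acts[[j]][[li]])
      }
    }
    M
  })
  names(cka) <- layers
  summ <- data.frame(
    layer = layers,
    mean = vapply(cka, function(M) mean(upper_tri_vec(M)), numeric(1)),
    q01 = vapply(cka, function(M) stats::quantile(upper_tri_vec(M), 0.01), numeric(1)),
    q99 = vapply(cka, function(M) stats::quantile(upper_tri_vec(M), 0.99), numeric(1))
  )
  structure(
    list(models = models, cka = cka, summary = summ,
         representative = which.min(val_rmse), val_rmse = val_rmse),
    class = "cka_population"
  )
}

#' @export
print.cka_population <- function(x, ...) {
  cat(sprintf("Network population: %d networks; representative = #%d\n",
              length(x$models), x$representative))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Check a network population for clustering structure
#'
#' Divisive hierarchical clustering on 1 - CKA distances, with elbow and
#' average-silhouette criteria over candidate partition sizes. The verdict
#' is "no significant clustering" when the best silhouette stays at or
#' below the threshold.
#'
#' @param cka_matrix symmetric pairwise CKA similarity matrix.
#' @param max_k largest partition size examined.
#' @param sil_threshold silhouette level counted as significant (default
#'   0.25).
#' @return list with `best_k`, `silhouette` (per k), `elbow_heights`,
#'   `significant` and `verdict`.
#' @export
network_cluster_check <- function(cka_matrix, max_k = 6, sil_threshold = 0.25) {
  n <- nrow(cka_matrix)
  if (n < 3) stop("need at least 3 networks")
  D <- 1 - cka_matrix
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dd <- stats::as.dist(D)
  di <- cluster::diana(dd, diss = TRUE)
  hc <- stats::as.hclust(di)
  ks <- 2:min(max_k, n - 1)
  sil <- vapply(ks, function(k) {
    cl <- stats::cutree(hc, k)
    if (length(unique(cl)) < 2) return(NA_real_)
    mean(cluster::silhouette(cl, dd)[, 3])
  }, numeric(1))
  heights <- rev(hc$height)
  best <- ks[which.max(sil)]
  significant <- any(sil > sil_threshold, na.rm = TRUE)
  list(
    best_k = if (significant) best else 1L,
    silhouette = stats::setNames(sil, ks),
    elbow_heights = heights,
    significant = significant,
    verdict = if (significant) {
      sprintf("clustering detected (k = %d, silhouette %.2f)", best, max(sil, na.rm = TRUE))
    } else {
      "no significant clustering"
    }
  )
}

#' Behavioural comparison statistics
#'
#' Compares a prediction vector against the human mean rating and the
#' physical truth: RMSE (and percent of the 16-step scale), Pearson
#' correlation, and partial correlations in two conventions — (B) the
#' correlation with the human mean controlling for the physical truth (and
#' with the truth controlling for nothing), and (C) each of human mean /
#' physical truth controlling for the other. Values are averaged across
#' scene variations first by default.
#'
#' @param predictions predicted viscosity per stimulus.
#' @param human_mean mean observer rating per stimulus.
#' @param physical physical viscosity step per stimulus.
#' @param design optional `stimulus_design` enabling variation averaging.
#' @param average_variations average within (scene, step) cells first
#'   (default TRUE when a design is given).
#' @param n_steps rating-scale length for the percent conversion.
#' @return a `comparison_stats` list.
#' @export
behavior_compare <- function(predictions, human_mean, physical, design = NULL,
                             average_variations = !is.null(design),
                             n_steps = 16) {
  stopifnot(length(predictions) == length(human_mean),
            length(predictions) == length(physical))
  if (average_variations) {
    if (is.null(design)) stop("variation averaging needs the design")
    predictions <- average_variations(predictions, design)$value
    human_mean <- average_variations(human_mean, design)$value
    physical <- average_variations(physical, design)$value
  }
  n <- length(predictions)
  if (n < 3) stop("insufficient data: need at least 3 stimuli")
  resid_on <- function(y, z) stats::resid(stats::lm(y ~ z))
  partial <- function(x, y, z) stats::cor(resid_on(x, z), resid_on(y, z))
  rm_h <- rmse(predictions, human_mean)
  rm_p <- rmse(predictions, physical)
  structure(list(
    n = n,
    rmse_human = rm_h,
    rmse_physical = rm_p,
    rmse_human_percent = percent_of_scale(rm_h, n_steps),
    rmse_physical_percent = percent_of_scale(rm_p, n_steps),
    r_human = stats::cor(predictions, human_mean),
    r_physical = stats::cor(predictions, physical),
    # B-style: human-mean correlation with the physical truth partialled out
    r_human_partial_physical = partial(predictions, human_mean, physical),
    # C-style counterpart: physical correlation with the human mean
    # partialled out
    r_physical_partial_human = partial(predictions, physical, human_mean)
  ), class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf(
    paste0("Comparison over %d stimuli:\n",
           "  RMSE vs human mean  %.3f (%.2f%% of scale)\n",
           "  RMSE vs physical    %.3f (%.2f%% of scale)\n",
           "  r (human, physical) %.3f, %.3f\n",
           "  partial r: human|physical %.3f, physical|human %.3f\n"),
    x$n, x$rmse_human, x$rmse_human_percent, x$rmse_physical,
    x$rmse_physical_percent, x$r_human, x$r_physical,
    x$r_human_partial_physical, x$r_physical_partial_human
  ))
  invisible(x)
}

#' Bootstrap rating baseline
#'
#' A chance-level reference: each draw assigns every stimulus a rating
#' sampled with replacement from the pooled empirical rating distribution,
#' and is scored against the human mean (RMSE and Pearson r).
#'
#' @param ratings the ratings data frame from [simulate_observers()] (or any
#'   vector of ratings pooled over observers and stimuli).
#' @param human_mean per-stimulus mean rating.
#' @param n_draws bootstrap draws (default 1000).
#' @param seed seed.
#' @return list with `rmse` and `r` (per-draw vectors) and their means.
#' @export
bootstrap_baseline <- function(ratings, human_mean, n_draws = 1000, seed = 1L) {
  pool <- if (is.data.frame(ratings)) ratings$rating else as.numeric(ratings)
  if (!length(pool)) stop("empty rating pool")
  if (length(human_mean) < 2) stop("need at least 2 stimuli")
  r <- rng_stream(derive_seed(seed, 2002L))
  n <- length(human_mean)
  rms <- numeric(n_draws)
  rr <- numeric(n_draws)
  for (b in seq_len(n_draws)) {
    draw <- pool[r$int(n, length(pool))]
    rms[b] <- rmse(draw, human_mean)
    rr[b] <- if (stats::sd(draw) > 0) stats::cor(draw, human_mean) else 0
  }
  list(rmse = rms, r = rr, mean_rmse = mean(rms), mean_r = mean(rr))
}
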