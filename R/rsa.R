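# Representational similarity analysis: representational dissimilarity
# matrices (RDMs) under two distance conventions, rank-correlation
# comparison, RDM regression and predictor intercorrelations.

#' Build a representational dissimilarity matrix
#'
#' Pairwise dissimilarities between stimuli from per-stimulus feature
#' vectors. Unit-level analyses use Euclidean distance (defined even for
#' never-active units); layer-level analyses use one minus the Pearson
#' correlation between activation patterns. Single-value high-level
#' predictors always use absolute (Euclidean) differences, and the scene
#' predictor the binary same/different-class map.
#'
#' @param features stimuli x dims numeric matrix (multi-dimensional features
#'   flattened beforehand).
#' @param metric `"euclidean"`, `"one_minus_pearson"` or `"binary"`.
#' @return an `rdm` object: the n x n symmetric matrix with zero diagonal,
#'   with the metric recorded in `attr(, "metric")`.
#' @export
rdm_from_features <- function(features,
                              metric = c("euclidean", "one_minus_pearson", "binary")) {
  metric <- match.arg(metric)
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2) stop("need at least 2 stimuli")
  if (metric == "euclidean") {
    sq <- rowSums(features^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(features)
    m <- sqrt(pmax(d2, 0))
  } else if (metric == "binary") {
    m <- 1 * outer(features[, 1], features[, 1], "!=")
  } else {
    sds <- apply(features, 1, stats::sd)
    if (any(sds == 0)) {
      warning("constant feature vector(s) under one_minus_pearson; ",
              "affected entries set to NA")
    }
    m <- 1 - suppressWarnings(stats::cor(t(features)))
    m[!is.finite(m)] <- NA
  }
  diag(m) <- 0
  m <- (m + t(m)) / 2
  structure(m, metric = metric, class = c("rdm", "matrix"))
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d stimuli, metric %s\n", nrow(x), attr(x, "metric")))
  invisible(x)
}

#' Compare two RDMs by Spearman rank correlation
#'
#' Correlates the vectorised strict upper triangles with average-rank tie
#' handling. Invariant to any strictly increasing transform of either RDM.
#'
#' @param a,b `rdm` objects (or square matrices) over the same stimuli.
#' @return a list with `rho` and `n_pairs`.
#' @export
compare_rdms <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("alignment error: RDMs differ in size")
  va <- upper_tri_vec(unclass(a))
  vb <- upper_tri_vec(unclass(b))
  ok <- is.finite(va) & is.finite(vb)
  list(rho = stats::cor(va[ok], vb[ok], method = "spearman"),
       n_pairs = sum(ok))
}

#' Regress a target RDM on predictor RDMs
#'
#' Ordinary least squares of the target's upper triangle on the predictors'
#' upper triangles, with intercept; reports the coefficient of
#' determination. Rank-deficient (collinear) predictor sets are handled by
#' R's pivoting least squares with a warning.
#'
#' @param target an `rdm`.
#' @param predictors a list of `rdm`s on the same stimuli.
#' @return R-squared in `[0, 1]`.
#' @export
rdm_regression <- function(target, predictors) {
  if (!length(predictors)) stop("need at least one predictor RDM")
  y <- upper_tri_vec(unclass(target))
  X <- vapply(predictors, function(p) upper_tri_vec(unclass(p)), numeric(length(y)))
  ok <- is.finite(y) & apply(is.finite(X), 1, all)
  fit <- stats::lm(y[ok] ~ X[ok, , drop = FALSE])
  if (any(is.na(stats::coef(fit)))) {
    warning("rank-deficient predictor set; pivoted least-squares solution")
  }
  summary(fit)$r.squared
}

#' Predictor intercorrelation matrix
#'
#' Pairwise Spearman correlations between all predictor RDMs (symmetric,
#' unit diagonal).
#'
#' @param rdms named list of `rdm`s on one registry.
#' @return a k x k correlation matrix.
#' @export
predictor_intercorrelation <- function(rdms) {
  k <- length(rdms)
  out <- diag(1, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      out[i, j] <- out[j, i] <- compare_rdms(rdms[[i]], rdms[[j]])$rho
    }
  }
  dimnames(out) <- list(names(rdms), names(rdms))
  out
}

#' Build predictor RDMs from computed metrics
#'
#' Applies the distance convention of the analysis level: image metrics use
#' Euclidean distance at the unit level and one-minus-Pearson at the layer
#' level; high-level predictors always use Euclidean/binary distances.
#'
#' @param feats output of [compute_metrics()].
#' @param level `"unit"` or `"layer"`.
#' @return a named list of `rdm`s.
#' @export
predictor_rdms <- function(feats, level = c("unit", "layer")) {
  level <- match.arg(level)
  lapply(feats, function(f) {
    tag <- attr(f, "distance")
    if (identical(tag, "binary")) {
      rdm_from_features(f, "binary")
    } else if (identical(tag, "euclidean_always") || level == "unit") {
      rdm_from_features(f, "euclidean")
    } else {
      rdm_from_features(f, "one_minus_pearson")
    }
  })
}
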