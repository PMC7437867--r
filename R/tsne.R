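# A compact t-SNE implementation for the 2-D visualisation embeddings.
# Embeddings are for display only; all clustering happens in the original
# space.

#' 2-D stochastic neighbour embedding
#'
#' Standard t-SNE: Gaussian input affinities calibrated per point to a
#' target perplexity by bisection, Student-t output kernel, gradient descent
#' with momentum and early exaggeration. Deterministic under a fixed seed.
#'
#' @param x data matrix (rows = points).
#' @param perplexity target perplexity (reduced automatically for tiny sets).
#' @param n_iter gradient-descent iterations.
#' @param seed integer seed for the initial layout.
#' @return an n x 2 coordinate matrix.
#' @export
tsne_embed <- function(x, perplexity = 30, n_iter = 400, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 points")
  perplexity <- max(2, min(perplexity, floor((n - 1) / 3)))
  sq <- rowSums(x^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(x), 0)
  # per-point bandwidth by bisection on the entropy
  P <- matrix(0, n, n)
  target <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-20
    hi <- 1e20
    beta <- 1
    for (it in 1:50) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s <= 0) {
        hi <- beta
        beta <- (lo + hi) / 2
        next
      }
      p <- p / s
      ent <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(ent - target) < 1e-5) break
      if (ent > target) {
        lo <- beta
        beta <- if (hi >= 1e20) beta * 2 else (lo + hi) / 2
      } else {
        hi <- beta
        beta <- (lo + hi) / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  r <- rng_stream(derive_seed(seed, 9009L))
  Y <- matrix(r$norm(2 * n, 0, 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  eta <- 50
  ex_end <- max(50, round(n_iter / 4))
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= ex_end) 4 else 1
    sqy <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(0.01, ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8))
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == ex_end) momentum <- 0.8
  }
  Y
}
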