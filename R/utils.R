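# Shared internal helpers.

#' Derive a reproducible child seed from a base seed and integer tags
#'
#' Mixes a base seed with a sequence of integer identifiers (scene index,
#' viscosity step, ...) into a new 32-bit seed via a multiplicative hash.
#' Used so that every stimulus, observer and training run has its own stream
#' that is a pure function of the global seed and its design coordinates.
#'
#' @param seed base integer seed.
#' @param ... further integer tags.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  ids <- c(seed, unlist(list(...), use.names = FALSE))
  stopifnot(all(is.finite(ids)))
  m <- 2147483647 # 2^31 - 1, keeps products < 2^53 for exact doubles
  h <- 0
  for (v in ids) {
    h <- (h * 69069 + (as.numeric(v) %% m) + 1) %% m
  }
  as.integer(h)
}

#' Root mean square error
#' @param a,b numeric vectors of equal length.
#' @return a single non-negative number.
#' @keywords internal
rmse <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(mean((a - b)^2))
}

#' Convert an error on the 1-16 rating scale to percent of scale
#' @param x RMSE in rating units.
#' @param n_steps number of steps in the rating scale.
#' @return percentage of the scale.
#' @export
percent_of_scale <- function(x, n_steps = 16) x / n_steps * 100

# Strict upper triangle of a square matrix, row-major order (fixed for
# reproducibility of regression designs across calls).
upper_tri_vec <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  t(m)[lower.tri(m)]
}

# Clamp to a closed interval.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Rec. 709 / sRGB luminance of an RGB array with channels in the last margin.
luminance <- function(rgb) {
  d <- dim(rgb)
  stopifnot(d[length(d)] == 3L)
  n <- prod(d[-length(d)])
  m <- matrix(rgb, nrow = n, ncol = 3L)
  y <- m %*% c(0.2126, 0.7152, 0.0722)
  array(y, dim = d[-length(d)])
}

# Grayscale (luminance) frames of a movie clip: frames x h x w array.
clip_gray <- function(clip) {
  d <- dim(clip)
  out <- array(0, d[1:3])
  for (f in seq_len(d[1])) out[f, , ] <- luminance(clip[f, , , ])
  out
}
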