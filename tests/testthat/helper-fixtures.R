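# Shared fixtures (built once per test run) and independent brute-force
# oracles used across the suite.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small 4-scene x 4-step x 2-variation clip set with ratings and a briefly
# trained tiny network.
tiny_world <- function() {
  fixture("tiny_world", function() {
    d <- make_design(4, 4, 2, 1, global_seed = 3)
    cs <- simulate_clipset(d)
    obs <- simulate_observers(d, seed = 4)
    cfg <- slowfusion_config_small(conv_channels = c(4L, 4L, 4L), fc4_width = 8L)
    model <- sf_train(build_network(cfg, seed = 2), cs, d$viscosity_step,
                      val_ids = seq(1, 32, 4), epochs = 3, seed = 1)
    list(design = d, clips = cs, obs = obs, model = model, cfg = cfg)
  })
}

# A single deterministic clip.
tiny_clip <- function() {
  fixture("tiny_clip", function() {
    d <- make_design(2, 3, 1, 1, global_seed = 5)
    simulate_movie(d[4, ])
  })
}

# A textured test pattern translating 1 px/frame horizontally.
translating_clip <- function() {
  fixture("translating_clip", function() {
    set.seed(41)
    tex <- matrix(stats::runif(100 * 100), 100, 100)
    tex <- (tex + liquidperc:::box_sum(tex, 1) / 9) / 2
    clip <- array(0, c(20, 64, 64, 3))
    for (f in 1:20) for (k in 1:3) clip[f, , , k] <- tex[11:74, (11:74) + (f - 1)]
    structure(clip, class = "movie_clip")
  })
}

# --- independent oracles -----------------------------------------------------

naive_euclidean_rdm <- function(X) {
  n <- nrow(X)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    }
  }
  m
}

naive_one_minus_pearson_rdm <- function(X) {
  n <- nrow(X)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) m[i, j] <- 1 - stats::cor(X[i, ], X[j, ])
    }
  }
  m
}

# Spearman via explicit average ranks + Pearson formula.
naive_spearman <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Partial correlation via the recursive closed form.
naive_partial_cor <- function(x, y, z) {
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, z)
  ryz <- stats::cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Linear CKA via the expanded HSIC form with explicit centring matrices.
naive_linear_cka <- function(A, B) {
  n <- nrow(A)
  H <- diag(n) - matrix(1 / n, n, n)
  K <- A %*% t(A)
  L <- B %*% t(B)
  hsic <- function(K, L) sum(diag(K %*% H %*% L %*% H))
  hsic(K, L) / sqrt(hsic(K, K) * hsic(L, L))
}

# Sliding-window 3x3 range with edge replication.
naive_local_contrast <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      ys <- max(1, y - 1):min(h, y + 1)
      xs <- max(1, x - 1):min(w, x + 1)
      # edge replication pads with the border values, which never change
      # the min or max of the covered region
      out[y, x] <- max(m[ys, xs]) - min(m[ys, xs])
    }
  }
  out
}

naive_fd_bins <- function(x) {
  width <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (width <= 0) return(1L)
  max(1L, as.integer(ceiling((max(x) - min(x)) / width)))
}

# Reference sRGB (D65) -> CIELAB conversion from the standard formulas.
naive_srgb_to_lab <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.numeric(M %*% lin)
  wp <- c(0.95047, 1, 1.08883)
  fr <- xyz / wp
  f <- ifelse(fr > (6 / 29)^3, fr^(1 / 3), fr / (3 * (6 / 29)^2) + 4 / 29)
  c(116 * f[2] - 16, 500 * (f[1] - f[2]), 200 * (f[2] - f[3]))
}

# Adjusted Rand index from the contingency table.
naive_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
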