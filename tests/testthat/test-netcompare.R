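# CKA, network populations and clustering checks, behavioural statistics and
# the bootstrap baseline.

test_that("linear CKA matches the brute-force HSIC expansion", {
  set.seed(71)
  for (i in 1:5) {
    A <- matrix(stats::rnorm(4 * 2), 4, 2)
    B <- matrix(stats::rnorm(4 * 3), 4, 3)
    expect_equal(linear_cka(A, B), naive_linear_cka(A, B), tolerance = 1e-12)
  }
  for (i in 1:3) {
    A <- matrix(stats::rnorm(10 * 6), 10, 6)
    B <- matrix(stats::rnorm(10 * 9), 10, 9)
    expect_equal(linear_cka(A, B), naive_linear_cka(A, B), tolerance = 1e-10)
  }
})

test_that("CKA has its stated invariances and bounds", {
  set.seed(72)
  X <- matrix(stats::rnorm(12 * 5), 12, 5)
  expect_equal(linear_cka(X, X), 1, tolerance = 1e-12)
  Q <- qr.Q(qr(matrix(stats::rnorm(25), 5, 5)))
  expect_equal(linear_cka(X, X %*% Q), 1, tolerance = 1e-10)
  expect_equal(linear_cka(X, -2.7 * X), 1, tolerance = 1e-10)
  Y <- matrix(stats::rnorm(12 * 8), 12, 8)
  v <- linear_cka(X, Y)
  expect_gte(v, 0)
  expect_lte(v, 1)
  expect_error(linear_cka(X, matrix(0, 12, 3)), "all-zero")
  expect_error(linear_cka(X, Y[1:6, ]), "alignment")
})

test_that("identically seeded networks give CKA 1 at every layer", {
  tw <- tiny_world()
  sub <- structure(list(data = tw$clips$data[, 1:10], design = tw$design[1:10, ]),
                   class = "clipset")
  m1 <- build_network(tw$cfg, seed = 5)
  m2 <- build_network(tw$cfg, seed = 5)
  for (l in c("relu1", "relu3")) {
    a1 <- collect_activations(m1, sub, l)$resp
    a2 <- collect_activations(m2, sub, l)$resp
    expect_equal(linear_cka(a1, a2), 1, tolerance = 1e-12)
  }
})

test_that("network cluster check reports homogeneity and planted families", {
  # homogeneous population: high similarity everywhere
  set.seed(73)
  n <- 8
  hom <- matrix(0.9, n, n) + matrix(stats::runif(n * n, 0, 0.02), n, n)
  hom <- (hom + t(hom)) / 2
  diag(hom) <- 1
  chk <- network_cluster_check(hom)
  expect_false(chk$significant)
  expect_match(chk$verdict, "no significant clustering")
  # two planted families from distinct feature bases
  set.seed(74)
  base1 <- matrix(stats::rnorm(20 * 6), 20, 6)
  base2 <- matrix(stats::rnorm(20 * 6), 20, 6)
  mats <- c(lapply(1:4, function(i) base1 + 0.1 * matrix(stats::rnorm(120), 20)),
            lapply(1:4, function(i) base2 + 0.1 * matrix(stats::rnorm(120), 20)))
  K <- diag(1, 8)
  for (i in 1:8) for (j in 1:8) if (j > i) {
    K[i, j] <- K[j, i] <- linear_cka(mats[[i]], mats[[j]])
  }
  chk2 <- network_cluster_check(K)
  expect_true(chk2$significant)
  expect_equal(chk2$best_k, 2)
  expect_error(network_cluster_check(K[1:2, 1:2]), "at least 3")
})

test_that("behavioural statistics match their closed forms", {
  set.seed(75)
  n <- 40
  phys <- rep(1:8, 5)
  hum <- phys + stats::rnorm(n, 0, 1)
  # predictions identical to the human mean
  bc <- behavior_compare(hum, hum, phys)
  expect_equal(bc$rmse_human, 0)
  expect_equal(bc$r_human, 1)
  # percent-of-scale conversion checked at two reference value pairs
  expect_equal(percent_of_scale(3.75), 23.4, tolerance = 0.05)
  expect_equal(percent_of_scale(1.70), 10.63, tolerance = 0.05)
  expect_equal(percent_of_scale(1.50), 9.375, tolerance = 1e-12)
  # partial correlations equal the recursive closed form
  pred <- phys + stats::rnorm(n, 0, 1.5)
  bc2 <- behavior_compare(pred, hum, phys)
  expect_equal(bc2$r_human_partial_physical, naive_partial_cor(pred, hum, phys),
               tolerance = 1e-10)
  expect_equal(bc2$r_physical_partial_human, naive_partial_cor(pred, phys, hum),
               tolerance = 1e-10)
  expect_error(behavior_compare(pred[1:2], hum[1:2], phys[1:2]), "insufficient")
})

test_that("partial correlation estimation recovers a known trivariate structure", {
  # construct (x, y, z) with known partial correlation r(x, y | z) = 0.5
  set.seed(76)
  n <- 1e4
  z <- stats::rnorm(n)
  e1 <- stats::rnorm(n)
  e2 <- 0.5 * e1 + sqrt(1 - 0.25) * stats::rnorm(n)
  x <- z + e1
  y <- z + e2
  bc <- behavior_compare(x, y, z, average_variations = FALSE)
  expect_lt(abs(bc$r_human_partial_physical - 0.5), 0.03)
})

test_that("bootstrap baseline is chance-level and handles degenerate pools", {
  tw <- tiny_world()
  bb <- bootstrap_baseline(tw$obs$ratings, tw$obs$mean_rating,
                           n_draws = 400, seed = 1)
  expect_lte(abs(bb$mean_r), 0.05)
  expect_gt(bb$mean_rmse, 0)
  expect_equal(formals(bootstrap_baseline)$n_draws, 1000)
  # single constant rating: closed-form RMSE
  const <- data.frame(rating = rep(7, 50))
  bbc <- bootstrap_baseline(const, tw$obs$mean_rating, n_draws = 5, seed = 1)
  expect_equal(bbc$mean_rmse, sqrt(mean((tw$obs$mean_rating - 7)^2)),
               tolerance = 1e-12)
  expect_error(bootstrap_baseline(data.frame(rating = numeric(0)),
                                  tw$obs$mean_rating), "empty")
  bb2 <- bootstrap_baseline(tw$obs$ratings, tw$obs$mean_rating,
                            n_draws = 50, seed = 9)
  bb3 <- bootstrap_baseline(tw$obs$ratings, tw$obs$mean_rating,
                            n_draws = 50, seed = 9)
  expect_identical(bb2$rmse, bb3$rmse)
})

test_that("variance explained reads a regression and rejects permuted ratings", {
  d <- make_design(5, 8, 2, 1, global_seed = 4)
  mr <- d$viscosity_step + stats::rnorm(nrow(d), 0, 0.1)
  expect_gt(rating_variance_explained(mr, d$viscosity_step), 0.99)
  r2p <- vapply(1:20, function(s) {
    set.seed(400 + s)
    rating_variance_explained(sample(mr), d$viscosity_step)
  }, numeric(1))
  expect_lt(mean(r2p), 0.05)
})

test_that("variation averaging collapses to scene-by-step cells", {
  d <- make_design(3, 4, 5, 1, global_seed = 6)
  x <- stats::rnorm(nrow(d))
  av <- average_variations(x, d)
  expect_equal(nrow(av), 12)
  cell <- d$scene_class == 2 & d$viscosity_step == 3
  expect_equal(av$value[av$scene_class == 2 & av$viscosity_step == 3],
               mean(x[cell]))
})
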