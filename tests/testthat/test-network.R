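# Slow-fusion network: geometry, determinism, gradients, training,
# prediction transforms, activation capture and lesioning.

tiny_cfg <- function(...) {
  slowfusion_config(height = 16L, width = 16L, conv_channels = c(3L, 4L, 5L),
                    kernel = c(3L, 3L, 3L), conv_stride = c(2L, 1L, 1L),
                    input_pool = 1L, fc4_width = 7L, dropout = 0, ...)
}

rand_input <- function(cfg, B, seed = 9) {
  set.seed(seed)
  matrix(stats::runif(cfg$frames * cfg$height * cfg$width * cfg$channels * B),
         ncol = B)
}

test_that("default architecture registers the reference unit counts and geometry", {
  cfg <- slowfusion_config()
  m <- build_network(cfg, seed = 1)
  expect_equal(nrow(m$registry), 420)
  expect_equal(as.numeric(table(m$registry$layer)), c(256, 64, 100))
  expect_equal(cfg$n_pathways, c(4L, 3L, 1L)) # (20 - 8)/4 + 1 stage-1 pathways
  expect_equal(cfg$fc4_width, 4096L)
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$learning_rate, 1.110510e-5)
  expect_equal(cfg$momentum, 0.43325)
  expect_equal(cfg$l2, 4e-9)
  expect_equal(cfg$epochs, 30L)
})

test_that("temporal receptive fields are 8/12/20/20 frames", {
  cfg <- slowfusion_config()
  expect_equal(temporal_receptive_field(cfg, 1), 8L)
  expect_equal(temporal_receptive_field(cfg, 2), 12L)
  expect_equal(temporal_receptive_field(cfg, 3), 20L)
  expect_equal(temporal_receptive_field(cfg, 4), 20L)
  expect_error(temporal_receptive_field(cfg, 5), "unknown stage")
})

test_that("inconsistent temporal geometry is rejected", {
  expect_error(slowfusion_config(t_extent = c(7L, 11L, 20L)), "config error")
  expect_error(slowfusion_config(t_extent = c(8L, 13L, 20L)), "config error")
  expect_error(slowfusion_config(t_extent = c(8L, 12L, 19L)), "config error")
})

test_that("initialisation and evaluation are deterministic", {
  cfg <- tiny_cfg()
  m1 <- build_network(cfg, seed = 7)
  m2 <- build_network(cfg, seed = 7)
  expect_identical(m1$params, m2$params)
  X <- rand_input(cfg, 3)
  expect_identical(sf_forward(m1, X)$pred, sf_forward(m1, X)$pred)
})

test_that("analytic gradients match finite differences (shared and per-pathway banks)", {
  for (share in c(TRUE, FALSE)) {
    cfg <- tiny_cfg(share_pathway_filters = share)
    m <- build_network(cfg, seed = 2)
    X <- rand_input(cfg, 2, seed = 11)
    y <- c(4, 12)
    fw <- sf_forward(m, X, keep = TRUE)
    gr <- liquidperc:::sf_backward(m, fw, 2 * (fw$pred - y) / 2)
    loss <- function(mm) mean((sf_forward(mm, X)$pred - y)^2)
    eps <- 1e-6
    set.seed(5)
    for (nm in c("W1", "b2", "W3", "W4", "W5")) {
      ii <- sample(length(m$params[[nm]]), 3)
      num <- vapply(ii, function(i) {
        m2 <- m
        m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
        (loss(m2) - loss(m)) / eps
      }, numeric(1))
      expect_lt(max(abs(num - gr[[nm]][ii]) / (abs(gr[[nm]][ii]) + 1e-6)), 1e-3)
    }
  }
})

test_that("training fits a small set and zero learning rate leaves weights unchanged", {
  tw <- tiny_world()
  cs10 <- structure(list(data = tw$clips$data[, 1:10], design = tw$design[1:10, ]),
                    class = "clipset")
  y <- tw$design$viscosity_step[1:10]
  m0 <- build_network(tw$cfg, seed = 6)
  pre <- rmse(predict(m0, cs10), y)
  mt <- sf_train(m0, cs10, y, val_ids = 1:2, epochs = 60, seed = 2)
  expect_lt(tail(mt$history$train_rmse, 1), pre)
  expect_equal(nrow(mt$history), 60)
  expect_true(all(mt$history$train_rmse >= 0))

  frozen_cfg <- tw$cfg
  frozen_cfg$learning_rate <- 0
  frozen_cfg$l2 <- 0
  mf <- build_network(frozen_cfg, seed = 6)
  mf2 <- sf_train(mf, cs10, y, val_ids = 1:2, epochs = 2, seed = 2)
  expect_identical(mf$params, mf2$params)
  expect_error(sf_train(m0, cs10, y + 20, val_ids = 1:2, epochs = 1), "1..16")
})

test_that("an entire scene class can be excluded from training", {
  tw <- tiny_world()
  m <- sf_train(build_network(tw$cfg, seed = 3), tw$clips,
                tw$design$viscosity_step, val_ids = 1:4,
                exclude_scene = 2, epochs = 1, seed = 1)
  expect_false(any(tw$design$scene_class[m$train_ids] == 2))
})

test_that("prediction is per-clip, duplicate-consistent and grayscale-idempotent", {
  tw <- tiny_world()
  p <- predict(tw$model, tw$clips)
  expect_equal(length(p), length(tw$clips))
  expect_true(all(is.finite(p)))
  one <- get_clip(tw$clips, 5)
  dup <- predict(tw$model, list(one, one))
  expect_equal(dup[1], dup[2])
  # a clip that is already gray is unchanged by the grayscale transform
  g <- liquidperc:::clip_gray(one)
  gray_clip <- structure(array(rep(as.numeric(g), 3),
                               c(20, 64, 64, 3)), class = "movie_clip")
  expect_equal(predict(tw$model, gray_clip, transform = "grayscale"),
               predict(tw$model, gray_clip), tolerance = 1e-10)
})

test_that("activation capture matches the unit registry and flags dead units", {
  tw <- tiny_world()
  for (li in 1:3) {
    act <- collect_activations(tw$model, tw$clips, paste0("relu", li))
    expect_equal(length(act$units), tw$cfg$conv_channels[li])
    expect_true(all(act$resp >= 0))
    expect_equal(ncol(act$pooled), tw$cfg$conv_channels[li])
  }
  # an all-zero input with zeroed biases gives all-zero ReLU responses
  m0 <- build_network(tiny_cfg(), seed = 1)
  m0$mean_pixel <- 0
  X0 <- matrix(0, 16 * 16 * 3 * 20, 2)
  fw <- sf_forward(m0, X0, want_acts = TRUE)
  expect_true(all(fw$relu1 == 0))
  expect_true(all(fw$relu2 >= 0))
})

test_that("lesioning is non-destructive, composable and silences stage 3", {
  cfg <- tiny_cfg()
  m <- build_network(cfg, seed = 4)
  X <- rand_input(cfg, 3)
  base <- sf_forward(m, X)$pred
  expect_equal(sf_forward(lesion_units(m, integer(0)), X)$pred, base)
  u3 <- m$registry$unit[m$registry$layer == 3]
  ml <- lesion_units(m, u3)
  expect_equal(sd(sf_forward(ml, X)$pred), 0) # constant output
  expect_equal(sf_forward(m, X)$pred, base) # original untouched
  ab <- lesion_units(m, c(1, 5))
  a_then_b <- lesion_units(lesion_units(m, 1), 5)
  expect_equal(sf_forward(ab, X)$pred, sf_forward(a_then_b, X)$pred)
  expect_error(lesion_units(m, 999), "registry error")
})
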