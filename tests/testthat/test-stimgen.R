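# Stimulus design, viscosity scale, clip generator and observer model.

test_that("factorial design enumerates and counts correctly", {
  d <- make_design(10, 16, 5, 1)
  expect_equal(nrow(d), 800)
  expect_equal(attr(d, "n_unique_simulations"), 800)

  d2 <- make_design(3, 4, 2, 2, global_seed = 9)
  expect_equal(nrow(d2), 3 * 4 * 2 * 2)
  expect_equal(attr(d2, "n_unique_simulations"), 3 * 4 * 2)
  expect_equal(attr(d2, "n_frames"), nrow(d2) * 20)
  # unique identification and deterministic scene-major ordering
  key <- with(d2, paste(scene_class, viscosity_step, scene_variation, optical_variation))
  expect_false(any(duplicated(key)))
  expect_true(!is.unsorted(d2$scene_class))
  expect_identical(d2, make_design(3, 4, 2, 2, global_seed = 9))

  d3 <- make_design(1, 1, 1, 1)
  expect_equal(nrow(d3), 1)
  expect_error(make_design(0, 16, 5, 1), "invalid design")
})

test_that("the full-grid design reproduces the reference corpus size", {
  d <- make_design(10, 16, 125, 5)
  expect_equal(nrow(d), 100000)
  expect_equal(attr(d, "n_unique_simulations"), 20000)
  expect_equal(attr(d, "n_frames"), 2e6)
})

test_that("viscosity scale is log-spaced with the stated endpoints", {
  sc <- viscosity_scale()
  expect_equal(viscosity_value(1, sc), 0.001, tolerance = 1e-12)
  expect_equal(viscosity_value(16, sc), 10, tolerance = 1e-12)
  # closed form evaluated independently
  expect_equal(viscosity_value(8, sc), 0.001 * 10^(4 * 7 / 15), tolerance = 1e-12)
  v <- viscosity_value(1:16, sc)
  ratios <- v[-1] / v[-16]
  expect_true(all(abs(ratios / ratios[1] - 1) < 1e-12))
  expect_true(all(diff(v) > 0))
  expect_error(viscosity_value(0, sc), "step")
  expect_error(viscosity_value(17, sc), "step")
})

test_that("clip generation is deterministic, bounded and shape-correct", {
  d <- make_design(10, 3, 1, 1, global_seed = 8)
  for (i in c(1, 14, 30)) { # three different scenes
    cl <- simulate_movie(d[i, ])
    expect_equal(dim(cl), c(20, 64, 64, 3))
    expect_true(all(is.finite(cl)))
    expect_true(min(cl) >= 0 && max(cl) <= 1)
  }
  c1 <- simulate_movie(d[5, ])
  c2 <- simulate_movie(d[5, ])
  expect_identical(unclass(c1), unclass(c2))
  bad <- d[1, ]
  bad$scene_class <- 99L
  expect_error(simulate_movie(bad), "scene")
})

test_that("reference set holds nuisance parameters at canonical values", {
  scale3 <- viscosity_scale(n_steps = 3)
  ref <- make_reference_set(scale3, global_seed = 2)
  expect_equal(length(ref), 10 * 3)
  # same scene, different viscosity: identical palette means a backdrop
  # region the liquid never reaches (top right, away from the pour stream)
  # is pixel-identical
  a <- get_clip(ref, 1)
  b <- get_clip(ref, 3)
  expect_identical(a[1, 1:3, 50:58, ], b[1, 1:3, 50:58, ])
  # but the clips as a whole differ between the extreme viscosities
  expect_gt(sum(abs(a - b)), 0)
})

test_that("default reference set has one clip per scene and step", {
  # counted via the design rather than rendering all 160 clips
  d <- make_design(10, 16, 1, 1)
  expect_equal(nrow(d), 160)
})

test_that("observer simulator is the identity without noise and calibrated by default", {
  d <- make_design(10, 16, 5, 1, global_seed = 1)
  id_model <- observer_model(scene_gain_sd = 0, scene_bias_sd = 0,
                             scene_gamma_sd = 0, observer_bias_sd = 0,
                             trial_noise_sd = 0)
  oz <- simulate_observers(d, model = id_model, seed = 1)
  expect_equal(oz$mean_rating, as.numeric(d$viscosity_step))
  expect_true(all(oz$ratings$rating >= 1 & oz$ratings$rating <= 16))
  expect_equal(nrow(oz$ratings), nrow(d) * 16)
  expect_false(any(duplicated(oz$ratings[c("observer_id", "stimulus_id")])))

  expect_error(observer_model(n_observers = 0), "observer")

  # default calibration: explained variance of the step in the band the
  # generator targets, averaged over seeds
  r2 <- vapply(1:10, function(s) {
    o <- simulate_observers(d, seed = s)
    av <- average_variations(o$mean_rating, d)
    rating_variance_explained(av$value, av$viscosity_step)
  }, numeric(1))
  expect_gte(mean(r2), 0.55)
  expect_lte(mean(r2), 0.80)

  o1 <- simulate_observers(d, seed = 3)
  o2 <- simulate_observers(d, seed = 3)
  expect_identical(o1$ratings$rating, o2$ratings$rating)
})

test_that("ratings table export round-trips", {
  tw <- tiny_world()
  path <- tempfile(fileext = ".tsv")
  write_ratings(tw$obs$ratings, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(tw$obs$ratings))
  expect_equal(back$rating, tw$obs$ratings$rating, tolerance = 1e-12)
  unlink(path)
})
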