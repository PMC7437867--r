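# Linear decoders, frozen-prefix head retraining, capacity and transfer
# experiments, layer profiles and stimulus embeddings.

test_that("the linear decoder solves a realizable problem almost exactly", {
  set.seed(61)
  X <- matrix(stats::rnorm(240 * 20), 240, 20)
  y <- as.numeric(X %*% stats::rnorm(20)) + 8
  dec <- fit_linear_decoder(X, y, epochs = 4000, seed = 1)
  expect_lte(dec$rmse, 1e-3)
  # degenerate columns warn but the decoder is still returned
  Xz <- cbind(X, 0)
  expect_warning(decz <- fit_linear_decoder(Xz, y, epochs = 200, seed = 1),
                 "degenerate")
  expect_true(is.finite(decz$rmse))
  # pure-noise activations decode at chance (near the target spread)
  yn <- stats::rnorm(240, 8, 2)
  Xn <- matrix(stats::rnorm(240 * 20), 240, 20)
  decn <- fit_linear_decoder(Xn, yn, epochs = 300, seed = 1)
  expect_equal(decn$rmse, 2, tolerance = 0.5)
})

test_that("head retraining keeps the prefix bit-identical and selects the best run", {
  tw <- tiny_world()
  rt <- retrain_head(tw$model, tw$clips, tw$design$viscosity_step,
                     val_ids = seq(1, 32, 4), width = 4, repeats = 3,
                     epochs = 5, seed = 2)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    expect_identical(rt$params[[nm]], tw$model$params[[nm]])
  }
  expect_equal(rt$config$fc4_width, 4L)
  expect_equal(length(rt$head_rmses), 3)
  expect_equal(min(rt$head_rmses),
               rmse(predict(rt, tw$clips)[seq(1, 32, 4)],
                    tw$design$viscosity_step[seq(1, 32, 4)]),
               tolerance = 0.3)
  expect_error(retrain_head(tw$model, tw$clips, tw$design$viscosity_step,
                            val_ids = 1:4, width = 0), "config error")
  # reference default repeat count
  expect_equal(formals(retrain_head)$repeats, 10)
})

test_that("scene transfer reports accuracy, AUC and normalised probabilities", {
  tw <- tiny_world()
  val <- seq(2, 32, 4) # every scene represented
  tr <- retrain_scene_head(tw$model, tw$clips, tw$design$scene_class, val,
                           epochs = 6, seed = 3)
  expect_gte(tr$accuracy, 0)
  expect_lte(tr$accuracy, 1)
  expect_equal(dim(tr$prob_matrix), c(4, 4))
  expect_equal(rowSums(tr$prob_matrix), rep(1, 4), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(retrain_scene_head(tw$model, tw$clips, rep(1L, 32), val),
               "classification error")
  expect_equal(formals(retrain_scene_head)$epochs, 8)
})

test_that("layer profiles correlate a layer with itself perfectly", {
  set.seed(62)
  resp <- matrix(stats::rnorm(14 * 9), 14, 9)
  act <- structure(list(layer = "relu2", resp = resp), class = "activation_record")
  self_rdm <- rdm_from_features(resp, "one_minus_pearson")
  lp <- layer_profile(act, list(self = self_rdm,
                                noise = rdm_from_features(matrix(stats::rnorm(14 * 9), 14))),
                      n_perm = 50, seed = 1)
  expect_equal(lp$rho[lp$predictor == "self"], 1, tolerance = 1e-12)
  expect_lte(lp$p[lp$predictor == "self"], 0.05)
  expect_gt(lp$p[lp$predictor == "noise"], 0.05)
})

test_that("decoder curve covers the four ReLU layers", {
  tw <- tiny_world()
  dc <- decoder_curve(tw$model, tw$clips, tw$obs$mean_rating, epochs = 60)
  expect_equal(dc$layer, c("relu1", "relu2", "relu3", "relu4"))
  expect_true(all(is.finite(dc$rmse)))
  expect_true(is.finite(attr(dc, "network_rmse")))
})

test_that("capacity experiment tracks widths with repeats and reference model", {
  tw <- tiny_world()
  cap <- capacity_experiment(tw$model, tw$clips, tw$design$viscosity_step,
                             val_ids = seq(1, 32, 4), widths = c(8, 15, 2),
                             repeats = 2, epochs = 4, seed = 1)
  expect_equal(sort(cap$width, decreasing = TRUE), cap$width)
  expect_true(all(cap$best_rmse <= cap$mean_rmse + 1e-12))
  ref <- attr(cap, "reference_model")
  expect_equal(ref$config$fc4_width, 15L)
  expect_identical(ref$params$W1, tw$model$params$W1)
  # default width grid includes the full head and 15 units
  expect_true(all(c(15) %in% eval(formals(capacity_experiment)$widths,
                                  list(model = tw$model))))
})

test_that("stimulus embedding places duplicates together and appends references", {
  tw <- tiny_world()
  ref <- structure(list(data = tw$clips$data[, 1:4], design = tw$design[1:4, ]),
                   class = "clipset")
  emb <- stimulus_embedding(tw$model, tw$clips, "relu3", reference = ref,
                            seed = 2, n_iter = 80)
  expect_equal(nrow(emb$coords), length(tw$clips) + 4)
  expect_equal(sum(emb$is_reference), 4)
  emb2 <- stimulus_embedding(tw$model, tw$clips, "relu3", reference = ref,
                             seed = 2, n_iter = 80)
  expect_identical(emb$coords, emb2$coords)
})
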