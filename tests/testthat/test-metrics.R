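# The predictor metrics: flow, histograms, spectra, contrast/gradient,
# colour channels, bank descriptors and high-level predictors.

test_that("optical flow recovers a known translation and has 19 slices", {
  clip <- translating_clip()
  fl <- optical_flow(clip, mask = matrix(TRUE, 64, 64))
  expect_equal(dim(fl), c(32, 32, 19))
  expect_equal(median(fl[fl > 0]), 1, tolerance = 0.2) # 1 px/frame
  # static clip: zero flow everywhere
  static <- clip
  for (f in 2:20) static[f, , , ] <- static[1, , , ]
  fs <- optical_flow(static)
  expect_equal(max(abs(fs)), 0)
  expect_error(optical_flow(array(0, c(1, 64, 64, 3))), "input error")
})

test_that("flow gradient and histograms behave and match the FD oracle", {
  fl <- optical_flow(tiny_clip())
  fg <- flow_gradient(fl)
  expect_equal(dim(fg), dim(fl))
  # constant flow field: gradient zero, histogram concentrated in one bin
  const <- array(0.7, c(32, 32, 19))
  expect_equal(max(flow_gradient(const)), 0)
  bins1 <- shared_flow_bins(list(const))
  h1 <- flow_hist(const, bins1)
  expect_true(all(colSums(h1 > 0) == 1))
  # conservation: every column counts all pixels
  bins <- shared_flow_bins(list(fl))
  h <- flow_hist(fl, bins)
  expect_true(all(colSums(h) == 32 * 32))
  # set-level bin count equals the rounded mean of per-stimulus FD counts
  set.seed(21)
  flows <- lapply(1:10, function(i) array(stats::rgamma(512, 2, 9), c(8, 8, 8)))
  expect_equal(shared_flow_bins(flows)$n_bins,
               as.integer(round(mean(vapply(flows, function(f) naive_fd_bins(as.numeric(f)),
                                            integer(1))))))
  expect_error(shared_flow_bins(list()), "empty")
})

test_that("power spectrum is rotationally binned with 33 entries per frame", {
  clip <- tiny_clip()
  ps <- power_spectrum(clip)
  expect_equal(dim(ps), c(33, 20))
  # constant frames: all power at radius zero
  flat <- structure(array(0.4, c(20, 64, 64, 3)), class = "movie_clip")
  psf <- power_spectrum(flat)
  expect_true(all(psf[1, ] > 0))
  expect_equal(max(psf[-1, ]), 0)
  # horizontal sinusoid at 5 cycles/image peaks in bin radius 5
  sin5 <- array(0, c(20, 64, 64, 3))
  wave <- matrix(sin(2 * pi * 5 * (0:63) / 64), 64, 64, byrow = TRUE)
  for (f in 1:20) for (k in 1:3) sin5[f, , , k] <- 0.5 + 0.4 * wave
  pss <- power_spectrum(structure(sin5, class = "movie_clip"))
  expect_equal(which.max(pss[-1, 1]), 5) # bins 1..32 after dropping DC
})

test_that("contrast and gradient match brute-force oracles", {
  clip <- tiny_clip()
  lc <- local_contrast(clip)
  expect_equal(dim(lc), c(64, 64, 20))
  g5 <- liquidperc:::clip_gray(clip)[5, , ]
  expect_equal(lc[, , 5], naive_local_contrast(g5), tolerance = 1e-12)
  # uniform frame: zero contrast; single bright pixel: contrast = intensity
  flat <- structure(array(0.3, c(20, 8, 8, 3)), class = "movie_clip")
  expect_equal(max(local_contrast(flat)), 0)
  spot <- array(0, c(20, 8, 8, 3))
  spot[, 4, 4, ] <- 0.8
  cs <- local_contrast(structure(spot, class = "movie_clip"))
  expect_equal(cs[4, 4, 1], 0.8, tolerance = 1e-9)
  ig <- image_gradient(clip)
  expect_equal(dim(ig), c(64, 64, 20))
  gx <- liquidperc:::central_diff(g5, 2)
  gy <- liquidperc:::central_diff(g5, 1)
  expect_equal(ig[, , 5], sqrt(gx^2 + gy^2), tolerance = 1e-12)
})

test_that("colour channels match reference colorimetry", {
  # gray pixels: zero saturation; white: L* = 100, a* = b* = 0
  gray <- structure(array(0.5, c(20, 4, 4, 3)), class = "movie_clip")
  cc <- colour_channels(gray)
  expect_equal(max(abs(cc$s_hsv)), 0)
  white <- structure(array(1, c(20, 4, 4, 3)), class = "movie_clip")
  cw <- colour_channels(white)
  expect_equal(cw$l_lab[1, 1, 1], 100, tolerance = 0.5)
  expect_equal(cw$a_lab[1, 1, 1], 0, tolerance = 0.5)
  expect_equal(cw$b_lab[1, 1, 1], 0, tolerance = 0.5)
  # random colours against the standard formulas
  set.seed(12)
  clip <- structure(array(stats::runif(20 * 4 * 4 * 3), c(20, 4, 4, 3)),
                    class = "movie_clip")
  cr <- colour_channels(clip)
  for (i in 1:5) {
    y <- sample(4, 1)
    x <- sample(4, 1)
    lab <- naive_srgb_to_lab(clip[3, y, x, ])
    expect_equal(c(cr$l_lab[y, x, 3], cr$a_lab[y, x, 3], cr$b_lab[y, x, 3]),
                 lab, tolerance = 1e-2)
  }
})

test_that("bank descriptors have registry dimensions and sane responses", {
  clip <- tiny_clip()
  gs <- gist(clip)
  expect_equal(dim(gs), c(512, 20))
  me <- motion_energy(clip)
  expect_equal(nrow(me), 128)
  sf <- sift_dense(clip)
  expect_equal(dim(sf), c(2048, 20))
  tx <- ps_texture(clip)
  expect_equal(dim(tx), c(119, 20))
  expect_true(all(is.finite(c(gs, me, sf, tx))))
  # static clip: opponent direction energies are balanced; a drifting
  # grating drives the matched direction harder than its opponent
  grating <- function(speed) {
    a <- array(0, c(20, 64, 64, 3))
    for (f in 1:20) {
      w <- matrix(sin(2 * pi * 8 * ((0:63) - speed * f) / 64), 64, 64, byrow = TRUE)
      for (k in 1:3) a[f, , , k] <- 0.5 + 0.4 * w
    }
    structure(a, class = "movie_clip")
  }
  ms <- rowMeans(motion_energy(grating(0)))
  md <- rowMeans(motion_energy(grating(2)))
  # direction channels come in opponent pairs of 4 grid cells
  pair_gap <- function(v) {
    e <- matrix(v, nrow = 4)
    abs(colSums(e)[seq(1, ncol(e), 2)] - colSums(e)[seq(2, ncol(e), 2)])
  }
  expect_gt(max(pair_gap(md)), max(pair_gap(ms)) * 2)
})

test_that("high-level predictors encode step, rating and scene structure", {
  tw <- tiny_world()
  hl <- high_level(tw$design, tw$obs$mean_rating)
  expect_equal(attr(hl$scene, "distance"), "binary")
  srdm <- rdm_from_features(hl$scene, "binary")
  same <- tw$design$scene_class[1] == tw$design$scene_class[2]
  expect_equal(srdm[1, 2], as.numeric(!same))
  vrdm <- rdm_from_features(hl$viscosity, "euclidean")
  i1 <- which(tw$design$viscosity_step == 1)[1]
  i4 <- which(tw$design$viscosity_step == 4)[1]
  expect_equal(vrdm[i1, i4], 3) # linear scale distance
  expect_equal(as.numeric(hl$perceived), tw$obs$mean_rating)
  expect_error(high_level(tw$design, 1:3), "coverage")
})

test_that("the metric driver covers the registry with matching shapes", {
  tw <- tiny_world()
  sub <- structure(list(data = tw$clips$data[, 1:6], design = tw$design[1:6, ]),
                   class = "clipset")
  feats <- compute_metrics(sub, tw$obs$mean_rating[1:6])
  reg <- metric_registry()
  expect_equal(names(feats), reg$name)
  expect_equal(ncol(feats$of_speed), 32 * 32 * 19)
  expect_equal(ncol(feats$power_spectrum), 33 * 20)
  expect_equal(ncol(feats$gist), 512 * 20)
  expect_equal(ncol(feats$contrast), 64 * 64 * 20)
  expect_equal(nrow(feats$of_speed), 6)
  # determinism of the whole driver
  feats2 <- compute_metrics(sub, tw$obs$mean_rating[1:6])
  expect_identical(feats$texture, feats2$texture)
})
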