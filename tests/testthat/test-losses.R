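# The four loss terms against closed forms and naive-loop oracles.

test_that("rgb_to_yuv implements the BT.601 matrix", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(rgb_to_yuv(px(0, 0, 0)), px(0, 0, 0))
  expect_equal(rgb_to_yuv(px(1, 1, 1)), px(1, 0, 0), tolerance = 1e-12)
  expect_equal(rgb_to_yuv(px(1, 0, 0)),
               px(0.299, -0.492 * 0.299, 0.877 * 0.701), tolerance = 1e-12)
  img <- random_image(5, 4, seed = 3)
  expect_equal(rgb_to_yuv(img), loop_yuv(img), tolerance = 1e-12)
})

test_that("fidelity loss: closed forms and loop oracle", {
  tr <- random_trace(4, 4, 3, seed = 10)
  for (t in 1:3) tr$b[[t]] <- tr$v[[t]]
  expect_equal(fidelity_loss(tr), 0)

  tr1 <- random_trace(1, 1, 1, seed = 11)
  tr1$b[[1]][] <- 0.5
  tr1$v[[1]][] <- 0.3
  expect_equal(fidelity_loss(tr1), 0.04, tolerance = 1e-12)

  tr3 <- random_trace(4, 4, 3, seed = 12)
  expect_equal(fidelity_loss(tr3), loop_fidelity(tr3$b, tr3$v), tolerance = 1e-12)
})

test_that("smoothness loss: degenerate cases and loop oracle", {
  tr <- random_trace(5, 5, 1, seed = 20)
  tr$b[[1]][] <- 0.7
  expect_equal(smoothness_loss(tr), 0)

  tr1 <- random_trace(1, 1, 1, seed = 21)   # no neighbours in a 1x1 image
  expect_equal(smoothness_loss(tr1), 0)

  tr2 <- random_trace(5, 5, 1, seed = 22)
  w <- loss_weights(sigma = 0.1)
  expect_equal(smoothness_loss(tr2, w),
               loop_smoothness(tr2$b, tr2$v, 0.1, 2L), tolerance = 1e-9)
})

test_that("smoothness weights are 1 on the diagonal, in (0,1], symmetric", {
  set.seed(30)
  yuv <- rgb_to_yuv(random_image(6, 6))
  sigma <- 0.1
  wij <- function(p, q) {
    exp(-sum((yuv[p[1], p[2], ] - yuv[q[1], q[2], ])^2) / (2 * sigma^2))
  }
  for (rep in 1:20) {
    p <- c(sample(6, 1), sample(6, 1))
    q <- c(sample(6, 1), sample(6, 1))
    expect_equal(wij(p, p), 1)
    expect_gt(wij(p, q), 0)
    expect_lte(wij(p, q), 1)
    expect_equal(wij(p, q), wij(q, p))
  }
})

test_that("perceptual loss equals fidelity with identity extractor, conv oracle otherwise", {
  tr <- random_trace(4, 4, 2, seed = 40)
  expect_identical(perceptual_loss(tr, feature_extractor("identity")),
                   fidelity_loss(tr))
  for (t in 1:2) tr$b[[t]] <- tr$v[[t]]
  expect_equal(perceptual_loss(tr, feature_extractor("random")), 0)

  # a single fixed 3x3 conv with known weights, against a hand-convolution
  set.seed(41)
  W <- matrix(rnorm(27 * 2), nrow = 27)
  bias <- c(0.1, -0.2)
  V1 <- structure(list(kind = "random", provenance = "seeded-random",
                       kernel = 3L,
                       layers = list(list(par = list(W = W, b = bias),
                                          act = "linear"))),
                  class = "feature_extractor")
  tr2 <- random_trace(4, 4, 2, seed = 42)
  expect_equal(perceptual_loss(tr2, V1),
               loop_perceptual_1conv(tr2$b, tr2$v, W, bias), tolerance = 1e-10)
})

test_that("gradient loss: constants, a 2x2 closed form, and the loop oracle", {
  tr <- random_trace(5, 5, 2, seed = 50)
  for (t in 1:2) tr$a[[t]][] <- 0.4
  expect_equal(gradient_loss(tr), 0)

  tr2 <- random_trace(2, 2, 1, seed = 51)
  for (ch in 1:3) tr2$a[[1]][, , ch] <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(gradient_loss(tr2), 0.5, tolerance = 1e-12)

  tr3 <- random_trace(6, 6, 2, seed = 52)
  expect_equal(gradient_loss(tr3), loop_gradient(tr3$a), tolerance = 1e-10)
})

test_that("all four terms match their loop oracles on many random small traces", {
  V <- feature_extractor("identity")
  set.seed(60)
  seeds <- sample.int(1e6, 50)
  for (s in seeds) {
    h <- sample(3:6, 1); w <- sample(3:6, 1); T <- sample(1:3, 1)
    tr <- random_trace(h, w, T, seed = s)
    expect_equal(fidelity_loss(tr), loop_fidelity(tr$b, tr$v),
                 tolerance = 1e-6)
    expect_equal(smoothness_loss(tr), loop_smoothness(tr$b, tr$v, 0.1, 2L),
                 tolerance = 1e-6)
    expect_equal(gradient_loss(tr), loop_gradient(tr$a), tolerance = 1e-6)
    expect_identical(perceptual_loss(tr, V), fidelity_loss(tr))
  }
})

test_that("total loss combines the parts with the configured weights", {
  tr <- random_trace(5, 5, 2, seed = 70)
  w <- loss_weights(alpha = 2, beta = 0.5)
  br <- total_loss(tr, w, feature_extractor("identity"))
  expect_equal(br$total, 2 * br$l_f + 0.5 * br$l_s + br$l_sem + br$l_grad,
               tolerance = 1e-9)
  expect_true(all(c(br$l_f, br$l_s, br$l_sem, br$l_grad) >= 0))
  # defaults follow the published weighting
  wd <- loss_weights()
  expect_equal(wd$alpha, 1)
  expect_equal(wd$beta, 1.5)
  expect_equal(wd$window, 2L)
})

test_that("gradient loss decreases under Gaussian blurring", {
  ns <- asNamespace("scretinex")
  set.seed(80)
  for (rep in 1:20) {
    img <- random_image(12, 12)
    blurred <- img
    for (ch in 1:3) blurred[, , ch] <- ns$gaussian_blur(img[, , ch], 1.5)
    tr <- random_trace(12, 12, 1, seed = rep)
    tr$a[[1]] <- img
    trb <- tr
    trb$a[[1]] <- blurred
    expect_lt(gradient_loss(trb), gradient_loss(tr))
  }
})
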