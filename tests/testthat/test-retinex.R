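# The multi-stage decomposition engine: stage loop semantics, the
# single-stage deployment path, reconstruction identities, and divergence.

test_that("T = 1 trace equals the single-stage path field by field", {
  nets <- tiny_networks(seed = 3)
  c <- random_image(10, 8, 0, 0.5, seed = 4)
  tr <- decompose(c, nets$ienet, nets$scanet, T = 1)
  single <- enhance_single_stage(c, nets$ienet)
  expect_identical(tr$a[[1]], single$enhanced)
  expect_identical(tr$b[[1]], single$illumination)
  expect_identical(tr$clamped[[1]], single$clamped)
  expect_identical(tr$v[[1]], c)
})

test_that("single-stage output is bit-identical to stage 1 of a deep trace", {
  nets <- tiny_networks(seed = 8)
  c <- random_image(12, 12, 0, 0.4, seed = 5)
  tr <- decompose(c, nets$ienet, nets$scanet, T = 3)
  single <- enhance_single_stage(c, nets$ienet)
  expect_identical(single$enhanced, tr$a[[1]])
  expect_identical(single$illumination, tr$b[[1]])
})

test_that("decompose matches an independently coded per-pixel loop oracle", {
  nets <- tiny_networks(seed = 13)
  c <- random_image(8, 8, 0, 0.6, seed = 14)
  tr <- decompose(c, nets$ienet, nets$scanet, T = 3)
  oracle <- naive_decompose(c, nets$ienet, nets$scanet, T = 3)
  for (t in 1:3) {
    expect_equal(tr$v[[t]], oracle$v[[t]], tolerance = 1e-10)
    expect_equal(tr$u[[t]], oracle$u[[t]], tolerance = 1e-10)
    expect_equal(tr$b[[t]], oracle$b[[t]], tolerance = 1e-10)
    expect_equal(tr$a[[t]], oracle$a[[t]], tolerance = 1e-10)
    expect_equal(tr$d[[t]], oracle$d[[t]], tolerance = 1e-10)
  }
})

test_that("stage fields obey the loop identities", {
  nets <- tiny_networks(seed = 23)
  c <- random_image(9, 11, 0, 0.5, seed = 24)
  T <- 3
  tr <- decompose(c, nets$ienet, nets$scanet, T = T)
  eps <- EPS_ILLUM
  for (t in seq_len(T)) {
    # b = clamp(v + u)
    expect_equal(tr$b[[t]], pmin(pmax(tr$v[[t]] + tr$u[[t]], eps), 1),
                 tolerance = 1e-12)
    expect_true(all(tr$b[[t]] >= eps & tr$b[[t]] <= 1))
    # reconstruction where the clamp was inactive
    active <- !tr$clamped[[t]]
    expect_lt(max(abs((tr$a[[t]] * tr$b[[t]] - c)[active])), 1e-6)
    # v chains through the calibration map
    if (t > 1) {
      expect_equal(tr$v[[t]], c + tr$d[[t - 1]], tolerance = 1e-12)
    }
  }
})

test_that("default decompose runs the published stage count", {
  nets <- tiny_networks(seed = 1)
  c <- random_image(8, 8, 0, 0.3, seed = 2)
  tr <- decompose(c, nets$ienet, nets$scanet)
  expect_equal(tr$T, 3L)
  expect_length(tr$a, 3L)
})

test_that("enhancement brightens wherever illumination is a proper fraction", {
  nets <- tiny_networks(seed = 31)
  c <- random_image(10, 10, 0.05, 0.35, seed = 32)
  out <- enhance_single_stage(c, nets$ienet)
  expect_true(all(out$enhanced >= c - 1e-12))        # b <= 1 so a >= c
  expect_true(all(out$enhanced <= c / EPS_ILLUM + 1e-12))
})

test_that("zero observation yields zero enhancement regardless of weights", {
  nets <- tiny_networks(seed = 6)
  c <- array(0, dim = c(6, 6, 3))
  out <- enhance_single_stage(c, nets$ienet)
  expect_true(all(out$enhanced == 0))
})

test_that("forced illumination reproduces hand arithmetic", {
  # a zero-weight, zero-bias output head makes u = sigmoid(0) = 0.5 everywhere
  ie <- build_network(network_spec("ienet"), seed = 7)
  ie$params$conv_out$W[] <- 0
  ie$params$conv_out$b[] <- 0
  c <- array(0.25, dim = c(4, 4, 3))
  out <- enhance_single_stage(c, ie)
  expect_equal(out$illumination, array(0.75, dim = dim(c)), tolerance = 1e-12)
  expect_equal(out$enhanced, array(0.25 / 0.75, dim = dim(c)), tolerance = 1e-12)
  # spot pixels of a non-uniform image: b = clamp(c + 0.5), a = c / b
  c2 <- random_image(5, 5, 0, 1, seed = 8)
  out2 <- enhance_single_stage(c2, ie)
  for (px in list(c(1, 1, 1), c(3, 2, 2), c(5, 5, 3), c(2, 4, 1))) {
    cc <- c2[px[1], px[2], px[3]]
    bb <- min(max(cc + 0.5, EPS_ILLUM), 1)
    expect_equal(out2$enhanced[px[1], px[2], px[3]], cc / bb, tolerance = 1e-12)
  }
})

test_that("weight sharing: every stage sees identical parameters", {
  # the engine holds one parameter set; traces built from the same nets over
  # different stage counts must agree on their common prefix
  nets <- tiny_networks(seed = 17)
  c <- random_image(8, 8, 0, 0.5, seed = 18)
  t2 <- decompose(c, nets$ienet, nets$scanet, T = 2)
  t4 <- decompose(c, nets$ienet, nets$scanet, T = 4)
  for (t in 1:2) {
    expect_identical(t2$u[[t]], t4$u[[t]])
    expect_identical(t2$d[[t]], t4$d[[t]])
  }
})

test_that("input validation rejects malformed calls", {
  nets <- tiny_networks()
  c <- random_image(6, 6, seed = 1)
  expect_error(decompose(c, nets$ienet, nets$scanet, T = 0),
               class = "scretinex_config")
  expect_error(decompose(c * 4, nets$ienet, nets$scanet), class = "scretinex_input")
  expect_error(decompose(matrix(0.1, 4, 4), nets$ienet, nets$scanet),
               class = "scretinex_input")
  expect_error(decompose(c, nets$ienet, NULL, use_sca = TRUE),
               class = "scretinex_config")
})

test_that("stage_consistency measures mean squared stage differences", {
  tr <- random_trace(6, 6, 3, seed = 41)
  tr$a[[2]] <- tr$a[[1]]
  tr$a[[3]] <- tr$a[[1]] + 0.1
  expect_equal(stage_consistency(tr), c(0, 0.01), tolerance = 1e-12)
  tr1 <- random_trace(6, 6, 1, seed = 42)
  expect_error(stage_consistency(tr1), class = "scretinex_input")
})

test_that("ablation cascade feeds the previous illumination forward", {
  nets <- tiny_networks(seed = 51)
  c <- random_image(7, 7, 0, 0.5, seed = 52)
  tr <- decompose(c, nets$ienet, scanet = NULL, T = 3, use_sca = FALSE)
  for (t in 2:3) expect_identical(tr$v[[t]], tr$b[[t - 1]])
  expect_null(tr$d[[1]])
})
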