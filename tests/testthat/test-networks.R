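# IE-Net / SCA-Net construction, determinism, shape and range contracts,
# parameter counting, and the checkpoint container.

test_that("default specs follow the published architecture table", {
  ie <- network_spec("ienet")
  expect_equal(ie$hidden_channels, 3L)
  expect_equal(ie$n_blocks, 1L)
  sc <- network_spec("scanet")
  expect_equal(sc$hidden_channels, 16L)
  expect_equal(sc$n_blocks, 3L)
  expect_equal(ie$kernel %% 2L, 1L)
})

test_that("invalid specs are rejected", {
  expect_error(network_spec("ienet", hidden_channels = 0), "positive")
  expect_error(network_spec("scanet", n_blocks = -1), "positive")
  expect_error(network_spec("ienet", kernel = 4), "odd")
})

test_that("same seed gives identical networks and outputs, different seeds differ", {
  a <- build_network(network_spec("ienet"), seed = 11)
  b <- build_network(network_spec("ienet"), seed = 11)
  c <- build_network(network_spec("ienet"), seed = 12)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
  img <- random_image(9, 7, seed = 1)
  expect_identical(apply_network(a, img), apply_network(b, img))
})

test_that("both networks preserve spatial shape and map into (0,1)", {
  nets <- tiny_networks()
  set.seed(42)
  for (rep in 1:6) {
    h <- sample(1:32, 1); w <- sample(1:32, 1)
    img <- random_image(h, w)
    for (net in nets) {
      out <- apply_network(net, img)
      expect_identical(dim(out), c(h, w, 3L))
      expect_true(all(out > 0 & out < 1))
    }
  }
})

test_that("network forward matches the per-pixel loop oracle", {
  nets <- tiny_networks(seed = 5)
  img <- random_image(7, 6, seed = 9)
  for (net in nets) {
    expect_equal(apply_network(net, img), naive_net_forward(net, img),
                 tolerance = 1e-12)
  }
})

test_that("a single 3x3 conv layer 3->3 has 84 parameters", {
  # one conv contributes k^2*cin*cout weights + cout biases
  spec <- network_spec("ienet")
  k2 <- spec$kernel^2
  expect_equal(k2 * 3 * 3 + 3, 84)
})

test_that("default IE-Net parameter count rounds to the printed model size", {
  pc <- count_parameters(network_spec("ienet"))
  expect_equal(pc$count, 258L)
  expect_equal(round(pc$millions, 4), 0.0003)
  # conv-only count (without the batch-norm scale/shift) rounds identically
  expect_equal(round((pc$count - 2 * 3) / 1e6, 4), 0.0003)
})

test_that("SCA-Net parameter count equals by-hand per-layer summation", {
  # input conv 3->16: 9*3*16 + 16 = 448
  # each block: conv 9*16*16 + 16 = 2320, BN 2*16 = 32; three blocks
  # output conv 9*16*3 + 3 = 435
  by_hand <- 448 + 3 * (2320 + 32) + 435
  expect_equal(count_parameters(network_spec("scanet"))$count, by_hand)
  expect_equal(by_hand, 7939)
})

test_that("count_parameters matches the length of the flattened parameters", {
  ns <- asNamespace("scretinex")
  for (kind in c("ienet", "scanet")) {
    spec <- network_spec(kind)
    net <- build_network(spec, seed = 3)
    expect_equal(count_parameters(spec)$count,
                 length(ns$flatten_params(net$params)))
  }
})

test_that("checkpoints round-trip bitwise", {
  nets <- tiny_networks(seed = 21)
  ckpt <- make_checkpoint(nets$ienet, nets$scanet,
                          train_config = list(epochs = 3), seed = 21L)
  path <- file.path(withr::local_tempdir(), "model.ckpt")
  save_checkpoint(ckpt, path)
  back <- load_checkpoint(path)
  expect_identical(back$ienet_arrays, ckpt$ienet_arrays)
  expect_identical(back$scanet_arrays, ckpt$scanet_arrays)
  restored <- checkpoint_networks(back)
  expect_identical(restored$ienet$params, nets$ienet$params)
  expect_identical(restored$scanet$params, nets$scanet$params)
  expect_identical(restored$scanet$running, nets$scanet$running)
})

test_that("checkpoint loading validates architecture and detects corruption", {
  nets <- tiny_networks(seed = 2)
  ckpt <- make_checkpoint(nets$ienet, nets$scanet)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.ckpt")
  save_checkpoint(ckpt, path)

  expect_error(load_checkpoint(file.path(dir, "absent.ckpt")),
               class = "scretinex_io")
  expect_error(
    load_checkpoint(path, scanet_spec = network_spec("scanet")),  # 16ch/3blk
    class = "scretinex_spec_mismatch"
  )
  expect_s3_class(load_checkpoint(path, ienet_spec = network_spec("ienet")),
                  "sadp_checkpoint")

  lines <- readLines(path)
  writeLines(lines[1:(length(lines) - 3L)], path)
  expect_error(load_checkpoint(path), class = "scretinex_corrupt")
})
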