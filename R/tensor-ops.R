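# Minimal dense-tensor layer kit used by the two illumination networks.
#
# A batch of N images of size H x W x C is stored flat as a matrix with
# N*H*W rows (image-major; within an image, column-major over H x W as in a
# base-R array) and C columns.  All layer forward passes return the cache
# their analytic backward pass needs.

new_tensor <- function(x, n, h, w) {
  stopifnot(is.matrix(x), nrow(x) == n * h * w)
  list(x = x, n = n, h = h, w = w)
}

#' @noRd
tensor_from_images <- function(imgs) {
  d <- dim(imgs[[1]])
  x <- do.call(rbind, lapply(imgs, function(im) matrix(im, ncol = d[3])))
  new_tensor(x, length(imgs), d[1], d[2])
}

tensor_image <- function(t, i) {
  rows <- ((i - 1) * t$h * t$w + 1):(i * t$h * t$w)
  array(t$x[rows, ], dim = c(t$h, t$w, ncol(t$x)))
}

tensor_rows <- function(t, i) ((i - 1) * t$h * t$w + 1):(i * t$h * t$w)

# -- convolution ------------------------------------------------------------

# Offsets are enumerated row-major over (dy, dx); for offset o and input
# channel cin, the im2col column index is (o - 1) * Cin + cin.  Conv weights
# are stored as a (k^2 * Cin) x Cout matrix in the same convention.

conv_offsets <- function(k) {
  r <- (k - 1L) %/% 2L
  as.matrix(expand.grid(dx = -r:r, dy = -r:r))[, c("dy", "dx"), drop = FALSE]
}

conv_forward <- function(t, W, b, k) {
  y <- cpp_conv_forward(t$x, W, b, t$n, t$h, t$w, k)
  list(out = new_tensor(y, t$n, t$h, t$w),
       cache = list(x = t$x, k = k, cin = ncol(t$x)))
}

conv_backward <- function(gy, cache, W) {
  res <- cpp_conv_backward(cache$x, W, gy$x, gy$n, gy$h, gy$w, cache$k)
  list(gW = res$gW, gb = res$gb, gx = new_tensor(res$gx, gy$n, gy$h, gy$w))
}

# -- batch normalisation ----------------------------------------------------

# Per-channel statistics over every element of the batch tensor (N, H, W).
# Biased variance in the normaliser; running statistics use the same
# estimator with momentum 0.1.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(t, gamma, beta, run_mean, run_var, training) {
  if (training) {
    mu <- colMeans(t$x)
    xc <- sweep(t$x, 2L, mu, "-")
    v <- colMeans(xc * xc)
    new_mean <- (1 - BN_MOMENTUM) * run_mean + BN_MOMENTUM * mu
    new_var <- (1 - BN_MOMENTUM) * run_var + BN_MOMENTUM * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- sweep(t$x, 2L, mu, "-")
    new_mean <- run_mean
    new_var <- run_var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(xc, 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(
    out = new_tensor(y, t$n, t$h, t$w),
    cache = list(xhat = xhat, invstd = invstd, training = training),
    run_mean = new_mean, run_var = new_var
  )
}

bn_backward <- function(gy, cache, gamma) {
  xhat <- cache$xhat
  ggamma <- colSums(gy$x * xhat)
  gbeta <- colSums(gy$x)
  if (cache$training) {
    m <- nrow(gy$x)
    gx <- sweep(
      gy$x - matrix(gbeta / m, nrow = m, ncol = length(gbeta), byrow = TRUE) -
        sweep(xhat, 2L, ggamma / m, "*"),
      2L, gamma * cache$invstd, "*"
    )
  } else {
    gx <- sweep(gy$x, 2L, gamma * cache$invstd, "*")
  }
  list(ggamma = ggamma, gbeta = gbeta, gx = new_tensor(gx, gy$n, gy$h, gy$w))
}

# -- activations ------------------------------------------------------------

relu_forward <- function(t) {
  mask <- t$x > 0
  list(out = new_tensor(t$x * mask, t$n, t$h, t$w), cache = mask)
}

relu_backward <- function(gy, mask) new_tensor(gy$x * mask, gy$n, gy$h, gy$w)

sigmoid_forward <- function(t) {
  y <- 1 / (1 + exp(-t$x))
  list(out = new_tensor(y, t$n, t$h, t$w), cache = y)
}

sigmoid_backward <- function(gy, y) new_tensor(gy$x * y * (1 - y), gy$n, gy$h, gy$w)
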