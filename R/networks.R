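#' Architecture specification for the illumination networks
#'
#' Two small fully-convolutional networks drive the enhancement cascade:
#' IE-Net (`kind = "ienet"`), the residual illumination estimator applied at
#' every stage, and SCA-Net (`kind = "scanet"`), the self-calibration network
#' that maps an enhanced image to a correction of the stage input.  Both share
#' the same shape: an input 3x3 convolution with ReLU producing a feature map
#' `f1`, a stack of `n_blocks` 3x3 convolution + batch-norm + ReLU blocks
#' producing `f2`, an additive fusion `f1 + f2`, and a 3x3 output convolution
#' with a sigmoid head so every output lies in (0, 1).
#'
#' Defaults follow the published architecture table: IE-Net keeps 3 channels
#' throughout with a single conv block (3 conv layers in total, 258 trainable
#' scalars); SCA-Net widens to 16 channels and 3 conv blocks so it can resolve
#' the subtler differences between the raw image and each stage input.
#'
#' @param kind `"ienet"` or `"scanet"`.
#' @param in_channels Number of input channels (RGB, 3).
#' @param hidden_channels Feature channels inside the conv blocks; defaults to
#'   3 for IE-Net and 16 for SCA-Net.
#' @param n_blocks Number of conv+BN+ReLU blocks; defaults to 1 for IE-Net and
#'   3 for SCA-Net.
#' @param kernel Odd kernel size (default 3); odd so that symmetric zero
#'   padding preserves the spatial size at every layer.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(kind = c("ienet", "scanet"), in_channels = 3L,
                         hidden_channels = NULL, n_blocks = NULL, kernel = 3L) {
  kind <- match.arg(kind)
  if (is.null(hidden_channels)) {
    hidden_channels <- if (kind == "ienet") 3L else 16L
  }
  if (is.null(n_blocks)) {
    n_blocks <- if (kind == "ienet") 1L else 3L
  }
  in_channels <- as.integer(in_channels)
  hidden_channels <- as.integer(hidden_channels)
  n_blocks <- as.integer(n_blocks)
  kernel <- as.integer(kernel)
  if (in_channels < 1L || hidden_channels < 1L || n_blocks < 1L) {
    stop("network_spec: channel and block counts must be positive", call. = FALSE)
  }
  if (kernel < 1L || kernel %% 2L == 0L) {
    stop("network_spec: kernel size must be a positive odd integer", call. = FALSE)
  }
  structure(
    list(kind = kind, in_channels = in_channels,
         hidden_channels = hidden_channels, n_blocks = n_blocks,
         kernel = kernel, fusion = "add", head_activation = "sigmoid"),
    class = "network_spec"
  )
}

# sigmoid(-4) ~ 0.018: residual and calibration branches start near zero
HEAD_BIAS_INIT <- -4

spec_equal <- function(a, b) {
  identical(unclass(a)[c("kind", "in_channels", "hidden_channels",
                         "n_blocks", "kernel")],
            unclass(b)[c("kind", "in_channels", "hidden_channels",
                         "n_blocks", "kernel")])
}

#' Build a network from a specification
#'
#' Weights are initialised deterministically from `seed` with Kaiming
#' (fan-in) normal draws for convolution kernels, zero biases, and unit
#' scale / zero shift for batch norm.  The output-head bias starts at -4 so
#' the sigmoid head opens near zero: the residual map and the calibration
#' map both begin as small perturbations (the cascade starts near the
#' identity), which keeps the illumination map inside its responsive range
#' `(eps, 1)` instead of saturating the clamp — with a mid-range head the
#' clamp is active almost everywhere at the start and blocks the gradient.
#' Batch-norm running statistics start at mean 0, variance 1 and are only
#' updated by training-mode forward passes; single-image inference always
#' uses the frozen running statistics.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the weight initialisation.
#' @return An object of class `sadp_network`.
#' @export
build_network <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "network_spec"))
  k <- spec$kernel
  cin <- spec$in_channels
  ch <- spec$hidden_channels
  rng <- local({
    set.seed(as.integer(seed))
    function(n, fan_in) matrix(stats::rnorm(n, sd = sqrt(2 / fan_in)), nrow = fan_in)
  })
  conv_par <- function(c_in, c_out) {
    fan <- k * k * c_in
    list(W = rng(fan * c_out, fan), b = numeric(c_out))
  }
  params <- list(conv_in = conv_par(cin, ch))
  params$blocks <- lapply(seq_len(spec$n_blocks), function(i) {
    list(conv = conv_par(ch, ch), bn = list(gamma = rep(1, ch), beta = rep(0, ch)))
  })
  params$conv_out <- conv_par(ch, cin)
  params$conv_out$b <- rep(HEAD_BIAS_INIT, cin)
  running <- lapply(seq_len(spec$n_blocks), function(i) {
    list(mean = rep(0, ch), var = rep(1, ch))
  })
  structure(list(spec = spec, params = params, running = running, seed = as.integer(seed)),
            class = "sadp_network")
}

#' @export
print.sadp_network <- function(x, ...) {
  pc <- count_parameters(x$spec)
  cat(sprintf("<sadp_network %s: %d ch, %d block(s), %dx%d kernel, %d parameters (%.4f M)>\n",
              x$spec$kind, x$spec$hidden_channels, x$spec$n_blocks,
              x$spec$kernel, x$spec$kernel, pc$count, pc$millions))
  invisible(x)
}

# Forward pass on a batch tensor.  Returns the output tensor, the per-layer
# cache for backprop, and the network with updated running statistics (only
# changed when training = TRUE).
net_forward <- function(net, t, training = FALSE) {
  k <- net$spec$kernel
  p <- net$params
  cache <- list()

  cv <- conv_forward(t, p$conv_in$W, p$conv_in$b, k)
  rl <- relu_forward(cv$out)
  cache$conv_in <- cv$cache
  cache$relu_in <- rl$cache
  f1 <- rl$out

  h <- f1
  cache$blocks <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    bcv <- conv_forward(h, p$blocks[[i]]$conv$W, p$blocks[[i]]$conv$b, k)
    bn <- bn_forward(bcv$out, p$blocks[[i]]$bn$gamma, p$blocks[[i]]$bn$beta,
                     net$running[[i]]$mean, net$running[[i]]$var, training)
    brl <- relu_forward(bn$out)
    cache$blocks[[i]] <- list(conv = bcv$cache, bn = bn$cache, relu = brl$cache)
    net$running[[i]]$mean <- bn$run_mean
    net$running[[i]]$var <- bn$run_var
    h <- brl$out
  }
  f2 <- h

  fused <- new_tensor(f1$x + f2$x, t$n, t$h, t$w)
  co <- conv_forward(fused, p$conv_out$W, p$conv_out$b, k)
  sg <- sigmoid_forward(co$out)
  cache$conv_out <- co$cache
  cache$sigmoid <- sg$cache

  list(out = sg$out, cache = cache, net = net)
}

# Backward pass; returns gradients in the same structure as net$params plus
# the gradient with respect to the input tensor.
net_backward <- function(net, cache, gy) {
  p <- net$params
  g <- list()

  gco <- sigmoid_backward(gy, cache$sigmoid)
  cb <- conv_backward(gco, cache$conv_out, p$conv_out$W)
  g$conv_out <- list(W = cb$gW, b = cb$gb)
  gfused <- cb$gx

  gf2 <- gfused
  g$blocks <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    bc <- cache$blocks[[i]]
    grl <- relu_backward(gf2, bc$relu)
    gbn <- bn_backward(grl, bc$bn, p$blocks[[i]]$bn$gamma)
    gcv <- conv_backward(gbn$gx, bc$conv, p$blocks[[i]]$conv$W)
    g$blocks[[i]] <- list(conv = list(W = gcv$gW, b = gcv$gb),
                          bn = list(gamma = gbn$ggamma, beta = gbn$gbeta))
    gf2 <- gcv$gx
  }
  gf1 <- new_tensor(gfused$x + gf2$x, gy$n, gy$h, gy$w)

  gri <- relu_backward(gf1, cache$relu_in)
  gci <- conv_backward(gri, cache$conv_in, p$conv_in$W)
  g$conv_in <- list(W = gci$gW, b = gci$gb)

  # align element order with net$params so flatten_params() of both agree
  list(grads = g[c("conv_in", "blocks", "conv_out")], gx = gci$gx)
}

#' Count trainable parameters of a network architecture
#'
#' Counts every trainable scalar: convolution weights and biases plus the
#' batch-norm scale and shift of each conv block (running statistics are not
#' trainable and are excluded).  The default IE-Net has
#' 84 + 90 + 84 = 258 scalars, i.e. 0.0003 M after rounding to 4 decimals —
#' roughly one ten-thousandth the size of typical enhancement networks, which
#' is what makes millisecond-scale CPU inference possible.
#'
#' @param spec A [network_spec()] or a built [build_network()] object.
#' @return A list with `count` (integer) and `millions` (count / 1e6).
#' @export
count_parameters <- function(spec) {
  if (inherits(spec, "sadp_network")) spec <- spec$spec
  stopifnot(inherits(spec, "network_spec"))
  k2 <- spec$kernel^2
  cin <- spec$in_channels
  ch <- spec$hidden_channels
  n_in <- k2 * cin * ch + ch
  n_block <- (k2 * ch * ch + ch) + 2L * ch          # conv + BN gamma/beta
  n_out <- k2 * ch * cin + cin
  total <- n_in + spec$n_blocks * n_block + n_out
  list(count = as.integer(total), millions = total / 1e6)
}

# -- parameter flattening (shared by the optimiser and checkpoints) ---------

flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

unflatten_params <- function(flat, template) {
  pos <- 0L
  rebuild <- function(x) {
    if (is.list(x)) return(lapply(x, rebuild))
    n <- length(x)
    out <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  out <- rebuild(template)
  stopifnot(pos == length(flat))
  out
}

# Named flat weight arrays for the checkpoint container.
params_as_arrays <- function(net) {
  out <- list()
  out[["conv_in.W"]] <- as.numeric(net$params$conv_in$W)
  out[["conv_in.b"]] <- net$params$conv_in$b
  for (i in seq_along(net$params$blocks)) {
    b <- net$params$blocks[[i]]
    out[[sprintf("block%d.conv.W", i)]] <- as.numeric(b$conv$W)
    out[[sprintf("block%d.conv.b", i)]] <- b$conv$b
    out[[sprintf("block%d.bn.gamma", i)]] <- b$bn$gamma
    out[[sprintf("block%d.bn.beta", i)]] <- b$bn$beta
    out[[sprintf("block%d.bn.running_mean", i)]] <- net$running[[i]]$mean
    out[[sprintf("block%d.bn.running_var", i)]] <- net$running[[i]]$var
  }
  out[["conv_out.W"]] <- as.numeric(net$params$conv_out$W)
  out[["conv_out.b"]] <- net$params$conv_out$b
  out
}

arrays_into_network <- function(net, arrays) {
  k2 <- net$spec$kernel^2
  take <- function(name, len) {
    a <- arrays[[name]]
    if (is.null(a)) stop(sprintf("checkpoint is missing array '%s'", name), call. = FALSE)
    if (length(a) != len) {
      stop(sprintf("checkpoint array '%s' has length %d, expected %d",
                   name, length(a), len), call. = FALSE)
    }
    a
  }
  cin <- net$spec$in_channels
  ch <- net$spec$hidden_channels
  net$params$conv_in$W <- matrix(take("conv_in.W", k2 * cin * ch), nrow = k2 * cin)
  net$params$conv_in$b <- take("conv_in.b", ch)
  for (i in seq_along(net$params$blocks)) {
    net$params$blocks[[i]]$conv$W <-
      matrix(take(sprintf("block%d.conv.W", i), k2 * ch * ch), nrow = k2 * ch)
    net$params$blocks[[i]]$conv$b <- take(sprintf("block%d.conv.b", i), ch)
    net$params$blocks[[i]]$bn$gamma <- take(sprintf("block%d.bn.gamma", i), ch)
    net$params$blocks[[i]]$bn$beta <- take(sprintf("block%d.bn.beta", i), ch)
    net$running[[i]]$mean <- take(sprintf("block%d.bn.running_mean", i), ch)
    net$running[[i]]$var <- take(sprintf("block%d.bn.running_var", i), ch)
  }
  net$params$conv_out$W <- matrix(take("conv_out.W", k2 * ch * cin), nrow = k2 * ch)
  net$params$conv_out$b <- take("conv_out.b", cin)
  net
}

#' Apply a network to a single image
#'
#' Inference-mode forward pass (frozen batch-norm statistics).  Output has
#' the same height and width as the input and every element lies in (0, 1)
#' because of the sigmoid head.
#'
#' @param net A built [build_network()] object.
#' @param img An `H x W x 3` array.
#' @return An `H x W x 3` array in (0, 1).
#' @export
apply_network <- function(net, img) {
  stopifnot(inherits(net, "sadp_network"), length(dim(img)) == 3L)
  t <- tensor_from_images(list(img))
  out <- net_forward(net, t, training = FALSE)$out
  tensor_image(out, 1L)
}
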