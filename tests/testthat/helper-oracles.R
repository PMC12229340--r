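# Independent naive-loop oracles.  Everything here is written as plain
# per-pixel/per-element loops with no shared code paths with the package
# internals, so agreement is evidence of correctness, not of consistency.

# zero-padded k x k convolution, weight rows ordered offset-major
# (dx fastest, then dy), channel within offset -- the package's layout
naive_conv <- function(img, W, b, k = 3L) {
  h <- dim(img)[1]; w <- dim(img)[2]; cin <- dim(img)[3]
  cout <- ncol(W)
  r <- (k - 1L) %/% 2L
  out <- array(0, dim = c(h, w, cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        acc <- b[co]
        for (o in seq_len(k * k)) {
          dy <- (o - 1L) %/% k - r
          dx <- (o - 1L) %% k - r
          ii <- i + dy; jj <- j + dx
          if (ii >= 1L && ii <= h && jj >= 1L && jj <= w) {
            for (c in seq_len(cin)) {
              acc <- acc + W[(o - 1L) * cin + c, co] * img[ii, jj, c]
            }
          }
        }
        out[i, j, co] <- acc
      }
    }
  }
  out
}

naive_relu <- function(x) pmax(x, 0)
naive_sigmoid <- function(x) 1 / (1 + exp(-x))

# inference-mode forward pass of a built network (frozen BN statistics)
naive_net_forward <- function(net, img) {
  p <- net$params
  k <- net$spec$kernel
  f1 <- naive_relu(naive_conv(img, p$conv_in$W, p$conv_in$b, k))
  h <- f1
  for (i in seq_along(p$blocks)) {
    blk <- p$blocks[[i]]
    z <- naive_conv(h, blk$conv$W, blk$conv$b, k)
    rm <- net$running[[i]]$mean; rv <- net$running[[i]]$var
    for (c in seq_len(dim(z)[3])) {
      z[, , c] <- (z[, , c] - rm[c]) / sqrt(rv[c] + 1e-5) * blk$bn$gamma[c] +
        blk$bn$beta[c]
    }
    h <- naive_relu(z)
  }
  naive_sigmoid(naive_conv(f1 + h, p$conv_out$W, p$conv_out$b, k))
}

# the full stage loop, written independently from the engine
naive_decompose <- function(c, ienet, scanet, T, eps = 1e-4) {
  v <- c
  out <- list(v = list(), u = list(), b = list(), a = list(), d = list())
  for (t in seq_len(T)) {
    u <- naive_net_forward(ienet, v)
    b <- pmin(pmax(v + u, eps), 1)
    a <- c / b
    d <- naive_net_forward(scanet, a)
    out$v[[t]] <- v; out$u[[t]] <- u; out$b[[t]] <- b; out$a[[t]] <- a
    out$d[[t]] <- d
    v <- c + d
  }
  out
}

# -- loss-term oracles -------------------------------------------------------

loop_fidelity <- function(b_list, v_list) {
  total <- 0
  for (t in seq_along(b_list)) {
    b <- b_list[[t]]; v <- v_list[[t]]
    s <- 0
    for (i in seq_len(dim(b)[1])) for (j in seq_len(dim(b)[2]))
      for (c in seq_len(dim(b)[3])) s <- s + (b[i, j, c] - v[i, j, c])^2
    total <- total + s / length(b)
  }
  total
}

loop_yuv <- function(img) {
  out <- array(0, dim = dim(img))
  for (i in seq_len(dim(img)[1])) for (j in seq_len(dim(img)[2])) {
    r <- img[i, j, 1]; g <- img[i, j, 2]; b <- img[i, j, 3]
    y <- 0.299 * r + 0.587 * g + 0.114 * b
    out[i, j, 1] <- y
    out[i, j, 2] <- 0.492 * (b - y)
    out[i, j, 3] <- 0.877 * (r - y)
  }
  out
}

loop_smoothness <- function(b_list, v_list, sigma, window) {
  total <- 0
  for (t in seq_along(b_list)) {
    b <- b_list[[t]]
    yuv <- loop_yuv(v_list[[t]])
    h <- dim(b)[1]; w <- dim(b)[2]; nc <- dim(b)[3]
    s <- 0
    for (i in seq_len(h)) for (j in seq_len(w)) {
      for (di in -window:window) for (dj in -window:window) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > h || jj < 1 || jj > w) next
        d2 <- 0
        for (c in seq_len(nc)) d2 <- d2 + (yuv[i, j, c] - yuv[ii, jj, c])^2
        wij <- exp(-d2 / (2 * sigma^2))
        for (c in seq_len(nc)) {
          s <- s + wij * abs(b[i, j, c] - b[ii, jj, c]) / (nc * h * w)
        }
      }
    }
    total <- total + s
  }
  total
}

loop_gradient <- function(a_list) {
  total <- 0
  for (t in seq_along(a_list)) {
    a <- a_list[[t]]
    h <- dim(a)[1]; w <- dim(a)[2]; nc <- dim(a)[3]
    s <- 0
    for (c in seq_len(nc)) for (i in seq_len(h)) for (j in seq_len(w)) {
      gx <- if (j < w) a[i, j + 1, c] - a[i, j, c] else 0
      gy <- if (i < h) a[i + 1, j, c] - a[i, j, c] else 0
      s <- s + abs(gx) + abs(gy)
    }
    total <- total + s / (h * w * nc)
  }
  total
}

# squared feature distance under an explicit one-layer linear conv extractor
loop_perceptual_1conv <- function(b_list, v_list, W, bias, k = 3L) {
  total <- 0
  for (t in seq_along(b_list)) {
    fb <- naive_conv(b_list[[t]], W, bias, k)
    fv <- naive_conv(v_list[[t]], W, bias, k)
    total <- total + mean((fb - fv)^2)
  }
  total
}

# -- small fixtures ----------------------------------------------------------

random_image <- function(h, w, lo = 0, hi = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::runif(h * w * 3, lo, hi), dim = c(h, w, 3L))
}

tiny_networks <- function(seed = 1L) {
  list(
    ienet = build_network(network_spec("ienet"), seed = seed),
    scanet = build_network(network_spec("scanet", hidden_channels = 4L,
                                        n_blocks = 2L), seed = seed + 1L)
  )
}

# build a random trace object directly (fields need not be consistent with
# any network; loss functions only read the fields)
random_trace <- function(h, w, T, seed) {
  set.seed(seed)
  mk <- function(lo, hi) array(stats::runif(h * w * 3, lo, hi), dim = c(h, w, 3L))
  structure(
    list(c = mk(0, 0.4),
         v = lapply(seq_len(T), function(t) mk(0, 1.4)),
         u = lapply(seq_len(T), function(t) mk(0, 1)),
         b = lapply(seq_len(T), function(t) mk(0.1, 1)),
         a = lapply(seq_len(T), function(t) mk(0, 1.2)),
         d = lapply(seq_len(T), function(t) mk(0, 1)),
         clamped = lapply(seq_len(T), function(t) array(FALSE, c(h, w, 3L))),
         T = T, use_sca = TRUE),
    class = "stage_trace"
  )
}
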