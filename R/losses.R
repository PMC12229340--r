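# The four unsupervised loss terms and their weighted total:
#
#   L = alpha * L_f + beta * L_s + L_sem + L_grad
#
# L_f    fidelity: squared distance between each stage's illumination map and
#        its corrected input.
# L_s    edge-aware smoothness: bilateral-weighted absolute illumination
#        differences over 5x5 neighbourhoods, weights from the corrected
#        input in YUV space.
# L_sem  perceptual: squared distance between fixed-feature-extractor
#        representations of illumination and corrected input.
# L_grad gradient sparsity (L1 of forward differences) of the enhanced
#        image, suppressing amplified noise.
#
# Every term is normalised by element count so magnitudes are
# resolution-independent; the stage dimension remains a sum.

#' Loss weighting configuration
#'
#' @param alpha Weight on the fidelity term (default 1).
#' @param beta Weight on the smoothness term (default 1.5).
#' @param sigma Gaussian bandwidth of the bilateral smoothness weights, on
#'   `[0, 1]` YUV intensities (default 0.1, an edge-preserving bandwidth:
#'   intensity steps well above 0.1 are treated as edges and not smoothed
#'   across).
#' @param window Neighbourhood radius of the smoothness term (default 2,
#'   i.e. a 5x5 window).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1, beta = 1.5, sigma = 0.1, window = 2L) {
  if (alpha <= 0 || beta <= 0 || sigma <= 0) {
    scretinex_error("loss_weights: alpha, beta and sigma must be > 0",
                    "scretinex_config")
  }
  window <- as.integer(window)
  if (window < 1L) {
    scretinex_error("loss_weights: window radius must be >= 1", "scretinex_config")
  }
  structure(list(alpha = alpha, beta = beta, sigma = sigma, window = window),
            class = "loss_weights")
}

#' RGB to YUV conversion (BT.601)
#'
#' `Y = 0.299 R + 0.587 G + 0.114 B`, `U = 0.492 (B - Y)`,
#' `V = 0.877 (R - Y)`.  Used by the smoothness weights, whose similarity is
#' judged in YUV so that chroma edges count as edges too.
#'
#' @param img `H x W x 3` RGB array.
#' @return `H x W x 3` array with channels Y, U, V.
#' @export
rgb_to_yuv <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  u <- 0.492 * (img[, , 3] - y)
  v <- 0.877 * (img[, , 1] - y)
  out <- array(0, dim = dim(img))
  out[, , 1] <- y; out[, , 2] <- u; out[, , 3] <- v
  out
}

luminance <- function(img) {
  if (length(dim(img)) == 3L) {
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    img
  }
}

# window offsets excluding the centre, row-major over (dy, dx)
window_offsets <- function(radius) {
  g <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  g <- g[!(g$dx == 0 & g$dy == 0), c("dy", "dx")]
  as.matrix(g)
}

# -- per-image terms (value + gradient) -------------------------------------

fidelity_term <- function(b, v, want_grad = FALSE) {
  diff <- b - v
  out <- list(val = mean(diff^2))
  if (want_grad) {
    g <- 2 * diff / length(diff)
    out$gb <- g
    out$gv <- -g
  }
  out
}

# BT.601 forward matrix (rows Y, U, V); its transpose is the adjoint used
# when back-propagating through the colour conversion.
YUV_MATRIX <- rbind(
  c(0.299, 0.587, 0.114),
  0.492 * c(-0.299, -0.587, 1 - 0.114),
  0.877 * c(1 - 0.299, -0.587, -0.114)
)

# b, v: H x W x 3 arrays.  The bilateral weights are a function of v, so the
# gradient carries both paths: through |b_i - b_j| into b and through the
# Gaussian similarity weights (and the YUV conversion) into v.  The pixel
# loop runs in compiled code.
smoothness_term <- function(b, v, sigma, window, want_grad = FALSE) {
  h <- dim(b)[1]; w <- dim(b)[2]; nc <- dim(b)[3]
  yuv <- rgb_to_yuv(v)
  res <- cpp_smoothness(matrix(b, ncol = nc), matrix(yuv, ncol = nc),
                        h, w, sigma, as.integer(window), want_grad)
  out <- list(val = res$val)
  if (want_grad) {
    out$gb <- array(res$gb, dim = dim(b))
    gyuv <- res$gyuv
    gv <- array(0, dim = dim(b))
    for (ch in 1:3) {
      gv[, , ch] <- array(YUV_MATRIX[1L, ch] * gyuv[, 1L] +
                          YUV_MATRIX[2L, ch] * gyuv[, 2L] +
                          YUV_MATRIX[3L, ch] * gyuv[, 3L], dim = c(h, w))
    }
    out$gv <- gv
  }
  out
}

gradient_term <- function(a, want_grad = FALSE) {
  h <- dim(a)[1]; w <- dim(a)[2]; nc <- dim(a)[3]
  nel <- h * w * nc
  val <- 0
  ga <- if (want_grad) array(0, dim = dim(a)) else NULL
  for (ch in seq_len(nc)) {
    m <- a[, , ch]
    if (w > 1L) {
      dx <- m[, 2:w, drop = FALSE] - m[, 1:(w - 1L), drop = FALSE]
      val <- val + sum(abs(dx)) / nel
      if (want_grad) {
        s <- sign(dx) / nel
        ga[, 2:w, ch] <- ga[, 2:w, ch] + s
        ga[, 1:(w - 1L), ch] <- ga[, 1:(w - 1L), ch] - s
      }
    }
    if (h > 1L) {
      dy <- m[2:h, , drop = FALSE] - m[1:(h - 1L), , drop = FALSE]
      val <- val + sum(abs(dy)) / nel
      if (want_grad) {
        s <- sign(dy) / nel
        ga[2:h, , ch] <- ga[2:h, , ch] + s
        ga[1:(h - 1L), , ch] <- ga[1:(h - 1L), , ch] - s
      }
    }
  }
  out <- list(val = val)
  if (want_grad) out$ga <- ga
  out
}

# -- public per-trace losses ------------------------------------------------

check_trace <- function(trace) {
  stopifnot(inherits(trace, "stage_trace"))
  trace
}

# the loss anchor of stage t is the corrected input c + d_{t-1} (d_0 = 0);
# with the calibration bypassed d is identically zero, so every stage
# anchors to the raw observation
loss_anchor <- function(trace, t) {
  if (trace$use_sca) trace$v[[t]] else trace$c
}

#' Fidelity loss
#'
#' Sum over stages of the mean squared difference between the illumination
#' map `b_t` and the corrected input `v_t = c + d_{t-1}` (with `d_0 = 0`).
#' Anchors the illumination estimate to the observation without any paired
#' reference.
#'
#' @param trace A `stage_trace` from [decompose()].
#' @return Nonnegative scalar.
#' @export
fidelity_loss <- function(trace) {
  check_trace(trace)
  sum(vapply(seq_len(trace$T), function(t) {
    fidelity_term(trace$b[[t]], loss_anchor(trace, t))$val
  }, numeric(1)))
}

#' Edge-aware smoothness loss
#'
#' For each stage, bilateral weights
#' `w_ij = exp(-sum_ch (v_i - v_j)^2 / (2 sigma^2))` are computed from the
#' corrected input in YUV over a `(2 window + 1)^2` neighbourhood, and the
#' per-channel-averaged absolute illumination differences `|b_i - b_j|` are
#' accumulated, normalised by pixel count, then summed over stages.  Uniform
#' regions of the input demand a smooth illumination map; edges (large YUV
#' steps) get exponentially small weights and may remain sharp.
#'
#' @param trace A `stage_trace`.
#' @param weights A [loss_weights()] (only `sigma` and `window` are used).
#' @return Nonnegative scalar.
#' @export
smoothness_loss <- function(trace, weights = loss_weights()) {
  check_trace(trace)
  sum(vapply(seq_len(trace$T), function(t) {
    smoothness_term(trace$b[[t]], loss_anchor(trace, t), weights$sigma,
                    weights$window)$val
  }, numeric(1)))
}

#' Perceptual (feature-space) loss
#'
#' Sum over stages of the mean squared difference between the fixed feature
#' extractor's representations of `b_t` and `v_t`.  Matching in feature
#' space rather than pixel space preserves the structures downstream vision
#' tasks rely on.
#'
#' @param trace A `stage_trace`.
#' @param V A [feature_extractor()].
#' @return Nonnegative scalar.
#' @export
perceptual_loss <- function(trace, V = feature_extractor("identity")) {
  check_trace(trace)
  sum(vapply(seq_len(trace$T), function(t) {
    fb <- feat_forward(V, tensor_from_images(list(trace$b[[t]])))
    fv <- feat_forward(V, tensor_from_images(list(loss_anchor(trace, t))))
    mean((fb$out$x - fv$out$x)^2)
  }, numeric(1)))
}

#' Gradient (noise-suppression) loss
#'
#' Sum over stages of the mean absolute forward-difference gradient of the
#' enhanced image `a_t` (replicate edge handling: the last row/column
#' differences are zero).  Division by a small illumination map amplifies
#' sensor noise; penalising the enhanced image's gradients suppresses it.
#'
#' @param trace A `stage_trace`.
#' @return Nonnegative scalar.
#' @export
gradient_loss <- function(trace) {
  check_trace(trace)
  sum(vapply(seq_len(trace$T), function(t) {
    gradient_term(trace$a[[t]])$val
  }, numeric(1)))
}

#' Total training loss
#'
#' `L = alpha * L_f + beta * L_s + L_sem + L_grad`, all four terms computed
#' on the same trace.
#'
#' @param trace A `stage_trace`.
#' @param weights A [loss_weights()].
#' @param V A [feature_extractor()].
#' @return An object of class `loss_breakdown`: list with `l_f`, `l_s`,
#'   `l_sem`, `l_grad` and `total`.
#' @export
total_loss <- function(trace, weights = loss_weights(),
                       V = feature_extractor("random")) {
  check_trace(trace)
  br <- list(
    l_f = fidelity_loss(trace),
    l_s = smoothness_loss(trace, weights),
    l_sem = perceptual_loss(trace, V),
    l_grad = gradient_loss(trace)
  )
  br$total <- weights$alpha * br$l_f + weights$beta * br$l_s + br$l_sem + br$l_grad
  structure(br, class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss total %.6g  (fidelity %.6g, smoothness %.6g, perceptual %.6g, gradient %.6g)\n",
              x$total, x$l_f, x$l_s, x$l_sem, x$l_grad))
  invisible(x)
}
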