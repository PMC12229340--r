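# Multi-stage Retinex decomposition with weight sharing and self-calibration.
#
# Stage loop (v_1 = c, d_0 = 0):
#   u_t = IE-Net(v_t)                  residual illumination estimate
#   b_t = clamp(v_t + u_t, eps, 1)     illumination map
#   a_t = c / b_t                      enhanced (reflectance) image
#   d_t = SCA-Net(a_t)                 self-calibration map
#   v_{t+1} = c + d_t                  corrected input of the next stage
#
# The same IE-Net / SCA-Net parameters are applied at every stage.  Without
# self-calibration (the ablation mode) the literal cascade is used instead:
# the next stage consumes the current illumination map, v_{t+1} = b_t.

#' Illumination clamp floor
#'
#' Illumination maps are clamped to `[EPS_ILLUM, 1]` before the element-wise
#' division: the floor guards the division, the ceiling encodes that
#' illumination is a fraction of full light (dividing by > 1 would darken).
#' @export
EPS_ILLUM <- 1e-4

check_image <- function(c, arg = "c") {
  if (!is.array(c) || length(dim(c)) != 3L || dim(c)[3] != 3L) {
    scretinex_error(sprintf("%s must be an H x W x 3 array", arg), "scretinex_input")
  }
  if (dim(c)[1] < 1L || dim(c)[2] < 1L) {
    scretinex_error(sprintf("%s must have positive spatial size", arg), "scretinex_input")
  }
  if (anyNA(c) || min(c) < 0 || max(c) > 1) {
    scretinex_error(sprintf("%s must have finite values in [0, 1]", arg), "scretinex_input")
  }
  invisible(c)
}

# Batched engine forward used by both the public trace API and the trainer.
# `cs` is a batch tensor; returns per-stage tensors plus the layer caches
# needed for backprop and the networks with updated running statistics.
forward_trace <- function(cs, ienet, scanet, T, training = FALSE,
                          use_sca = TRUE, final_d = FALSE) {
  if (!is.numeric(T) || T < 1L) {
    scretinex_error("stage count T must be >= 1", "scretinex_config")
  }
  T <- as.integer(T)
  stages <- vector("list", T)
  v <- cs
  for (t in seq_len(T)) {
    ie <- net_forward(ienet, v, training)
    ienet <- ie$net
    u <- ie$out
    s <- v$x + u$x
    mask <- s > EPS_ILLUM & s < 1
    b <- new_tensor(pmin(pmax(s, EPS_ILLUM), 1), cs$n, cs$h, cs$w)
    a <- new_tensor(cs$x / b$x, cs$n, cs$h, cs$w)
    st <- list(v = v, u = u, b = b, a = a, mask = mask,
               ie_cache = ie$cache, d = NULL, sc_cache = NULL)
    if (use_sca && (t < T || final_d)) {
      sc <- net_forward(scanet, a, training)
      scanet <- sc$net
      st$d <- sc$out
      st$sc_cache <- sc$cache
    }
    stages[[t]] <- st
    v <- if (use_sca) {
      if (is.null(st$d)) v else new_tensor(cs$x + st$d$x, cs$n, cs$h, cs$w)
    } else {
      b
    }
  }
  list(c = cs, stages = stages, ienet = ienet, scanet = scanet, T = T,
       use_sca = use_sca)
}

batch_trace_to_stage_trace <- function(fw) {
  take <- function(field) {
    lapply(fw$stages, function(st) {
      x <- st[[field]]
      if (is.null(x)) return(NULL)
      tensor_image(x, 1L)
    })
  }
  structure(
    list(c = tensor_image(fw$c, 1L),
         v = take("v"), u = take("u"), b = take("b"), a = take("a"),
         d = take("d"),
         clamped = lapply(fw$stages, function(st) {
           array(!st$mask, dim = c(fw$c$h, fw$c$w, ncol(fw$c$x)))
         }),
         T = fw$T, use_sca = fw$use_sca),
    class = "stage_trace"
  )
}

#' Multi-stage Retinex decomposition of a low-light image
#'
#' Runs the full training-time cascade in inference mode (frozen batch-norm
#' statistics) and records every per-stage field: corrected input `v`,
#' residual `u`, illumination `b`, enhanced image `a`, calibration map `d`,
#' and the clamping mask.  Stage 1 always consumes the raw observation
#' (`v[[1]] == c`); with self-calibration each later stage consumes
#' `c + d` from the previous stage, without it the literal cascade feeds the
#' previous illumination map forward.
#'
#' @param c Observed low-light image, `H x W x 3` array in `[0, 1]`.
#' @param ienet,scanet Built networks ([build_network()]); `scanet` may be
#'   `NULL` when `use_sca = FALSE`.
#' @param T Number of stages (>= 1).
#' @param use_sca Apply the self-calibration module (default `TRUE`).
#' @return An object of class `stage_trace` with per-stage lists `v`, `u`,
#'   `b`, `a`, `d`, `clamped`.
#' @export
decompose <- function(c, ienet, scanet = NULL, T = 3L, use_sca = TRUE) {
  check_image(c)
  stopifnot(inherits(ienet, "sadp_network"))
  if (use_sca && !inherits(scanet, "sadp_network")) {
    scretinex_error("decompose with use_sca = TRUE needs a built SCA-Net",
                    "scretinex_config")
  }
  cs <- tensor_from_images(list(c))
  fw <- forward_trace(cs, ienet, scanet, T, training = FALSE,
                      use_sca = use_sca, final_d = TRUE)
  batch_trace_to_stage_trace(fw)
}

#' Single-stage enhancement (the deployment path)
#'
#' The production inference mode: one IE-Net pass on the raw image, clamp to
#' get the illumination map, divide to get the enhanced image.  The result is
#' bit-identical to stage 1 of [decompose()] with the same network.  The
#' enhanced image is returned unclipped (values can exceed 1 where the
#' illumination clamp was active); clipping to `[0, 1]` happens on image
#' export only.
#'
#' @param c Observed low-light image, `H x W x 3` array in `[0, 1]`.
#' @param ienet A built IE-Net.
#' @return A list with `enhanced` (a), `illumination` (b) and `clamped`
#'   (logical array, `TRUE` where the clamp was active).
#' @export
enhance_single_stage <- function(c, ienet) {
  check_image(c)
  stopifnot(inherits(ienet, "sadp_network"))
  cs <- tensor_from_images(list(c))
  fw <- forward_trace(cs, ienet, NULL, 1L, training = FALSE, use_sca = FALSE)
  st <- fw$stages[[1L]]
  list(enhanced = tensor_image(st$a, 1L),
       illumination = tensor_image(st$b, 1L),
       clamped = array(!st$mask, dim = dim(c)))
}

#' Per-stage divergence of the enhanced outputs
#'
#' Mean squared difference between the stage-1 enhanced image and each later
#' stage's enhanced image.  Small values certify that the cascade has
#' converged to a common state, i.e. that single-stage inference loses
#' nothing — the quantity the self-calibration module is designed to drive
#' to zero.
#'
#' @param trace A `stage_trace` with at least 2 stages.
#' @return Numeric vector of length `T - 1`: `mean((a_1 - a_t)^2)` for
#'   `t = 2..T`.
#' @export
stage_consistency <- function(trace) {
  stopifnot(inherits(trace, "stage_trace"))
  if (trace$T < 2L) {
    scretinex_error("stage_consistency needs a trace with T >= 2", "scretinex_input")
  }
  a1 <- trace$a[[1L]]
  vapply(2:trace$T, function(t) mean((a1 - trace$a[[t]])^2), numeric(1))
}
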