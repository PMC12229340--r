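# Reference-based evaluation against synthetic ground truth, plus the
# stage-convergence diagnostic.
#
# The published comparison metrics for this method family are no-reference
# image-quality models (HIGRADE, BRISQUE, CEIQ, ENIQA) with their own fitted
# parameters; those are third-party scoring models, not part of this
# package.  Because the synthetic scenes carry exact ground truth, quality
# here is assessed with full-reference metrics instead (PSNR, SSIM,
# illumination correlation), which is a stronger check where ground truth
# exists — but numbers are not comparable to published no-reference scores.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(1 / MSE)` with peak 1.  Identical images have no finite PSNR:
#' a flagged sentinel (`NA` with attribute `identical_images = TRUE`) is
#' returned rather than a number.
#'
#' @param x,ref Arrays of the same shape.
#' @return PSNR in dB, or the flagged sentinel.
#' @export
psnr <- function(x, ref) {
  if (!identical(dim(x), dim(ref))) {
    scretinex_error("psnr: images must have the same shape", "scretinex_input")
  }
  mse <- mean((x - ref)^2)
  if (mse == 0) {
    return(structure(NA_real_, identical_images = TRUE))
  }
  10 * log10(1 / mse)
}

#' Structural similarity index (SSIM)
#'
#' Standard single-scale SSIM on luminance with an 11x11 Gaussian window
#' (sigma 1.5), stabilisers `C1 = 0.01^2`, `C2 = 0.03^2`, data range 1.
#'
#' @param x,ref Arrays of the same shape (RGB arrays are converted to
#'   BT.601 luminance).
#' @return Mean SSIM over the image, in `[-1, 1]`; `ssim(x, x) == 1`.
#' @export
ssim <- function(x, ref) {
  if (!identical(dim(x), dim(ref))) {
    scretinex_error("ssim: images must have the same shape", "scretinex_input")
  }
  a <- luminance(x); b <- luminance(ref)
  c1 <- 0.01^2; c2 <- 0.03^2
  sig <- 1.5
  mu_a <- gaussian_blur(a, sig)
  mu_b <- gaussian_blur(b, sig)
  va <- gaussian_blur(a * a, sig) - mu_a^2
  vb <- gaussian_blur(b * b, sig) - mu_b^2
  cab <- gaussian_blur(a * b, sig) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
       ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(s)
}

#' Pearson correlation between estimated and ground-truth illumination
#'
#' The estimate's BT.601 luminance is correlated with the ground-truth
#' field over all pixels.  Pearson is affine-invariant, so a correct
#' illumination shape scores 1 regardless of global scale or offset — the
#' right yardstick, since the decomposition is only identifiable up to a
#' scale shared between the factors.
#'
#' @param b_est Estimated illumination, `H x W x 3` or `H x W`.
#' @param b_gt Ground-truth illumination, `H x W` (must be non-constant).
#' @return Correlation in `[-1, 1]`.
#' @export
illumination_recovery <- function(b_est, b_gt) {
  e <- luminance(b_est)
  g <- if (length(dim(b_gt)) == 3L) luminance(b_gt) else b_gt
  if (!identical(dim(e), dim(g))) {
    scretinex_error("illumination_recovery: shapes disagree", "scretinex_input")
  }
  if (stats::sd(as.numeric(g)) == 0) {
    scretinex_error("illumination_recovery: constant ground truth has undefined correlation",
                    "scretinex_input")
  }
  stats::cor(as.numeric(e), as.numeric(g))
}

#' Stage-convergence diagnostic for paired models
#'
#' Decomposes each image with both checkpoints and reports, per model, the
#' mean divergence between the stage-1 enhanced output and each later
#' stage's output.  A self-calibrated model should sit strictly below the
#' uncalibrated cascade at every stage: that ordering is what certifies
#' single-stage inference.
#'
#' @param ckpt_sca Checkpoint trained with self-calibration.
#' @param ckpt_nosca Checkpoint trained without it (ablation cascade).
#' @param images List of `H x W x 3` arrays.
#' @param T Number of stages to unroll (>= 2 for a non-empty report).
#' @return A data.frame with columns `model`, `stage`, `divergence`
#'   (plot-ready); zero rows with a `notice` attribute when `T = 1`.
#' @export
convergence_report <- function(ckpt_sca, ckpt_nosca, images, T = 3L) {
  stopifnot(inherits(ckpt_sca, "sadp_checkpoint"),
            inherits(ckpt_nosca, "sadp_checkpoint"))
  if (T < 2L) {
    out <- data.frame(model = character(), stage = integer(),
                      divergence = numeric())
    attr(out, "notice") <- "T = 1: single stage, no divergence to report"
    return(out)
  }
  one <- function(ckpt, label, use_sca) {
    nets <- checkpoint_networks(ckpt)
    acc <- numeric(T - 1L)
    for (img in images) {
      tr <- decompose(img, nets$ienet, nets$scanet, T = T, use_sca = use_sca)
      acc <- acc + stage_consistency(tr)
    }
    data.frame(model = label, stage = 2:T, divergence = acc / length(images))
  }
  rbind(one(ckpt_sca, "with_sca", TRUE),
        one(ckpt_nosca, "without_sca", FALSE))
}

#' Full-reference evaluation report on synthetic scenes
#'
#' Enhances each observation with the checkpoint's single-stage deployment
#' path and scores it against the scene's ground truth.
#'
#' @param ckpt An `sadp_checkpoint`.
#' @param triples List of `synthetic_triple`s.
#' @return A list with `per_image` (data.frame: psnr, ssim, brightness
#'   before/after, illumination correlation) and `summary` (means and sds).
#' @export
eval_report <- function(ckpt, triples) {
  stopifnot(inherits(ckpt, "sadp_checkpoint"))
  nets <- checkpoint_networks(ckpt)
  rows <- lapply(seq_along(triples), function(i) {
    tr <- triples[[i]]
    enh <- enhance_single_stage(tr$observation, nets$ienet)
    a <- clip01(enh$enhanced)
    p <- psnr(a, tr$reflectance_gt)
    data.frame(
      image = i,
      psnr = if (is.na(p)) Inf else as.numeric(p),
      ssim = ssim(a, tr$reflectance_gt),
      brightness_before = mean(tr$observation),
      brightness_after = mean(a),
      illum_correlation = illumination_recovery(enh$illumination, tr$illumination_gt)
    )
  })
  per_image <- do.call(rbind, rows)
  num <- per_image[, setdiff(names(per_image), "image")]
  summary <- data.frame(metric = names(num),
                        mean = vapply(num, mean, numeric(1)),
                        sd = vapply(num, stats::sd, numeric(1)),
                        row.names = NULL)
  list(per_image = per_image, summary = summary)
}
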