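# Synthetic low-light scenes with known ground truth.
#
# Scenes follow the Retinex generative model the enhancement method assumes:
# a reflectance image (textured background plus bright elliptical bodies,
# statistically emulating animals under a barn camera) is multiplied by a
# spatially smooth, channel-shared illumination field well below full light,
# and additive Gaussian read noise is applied after the product.  Because
# both factors are known, every downstream module can be scored against
# ground truth without any real data.

#' Synthetic scene specification
#'
#' @param height,width Image size in pixels (>= 8).
#' @param n_shapes Number of bright elliptical regions (default 3).
#' @param background_texture_scale Gaussian-blur bandwidth (pixels) of the
#'   background reflectance texture; larger values give lower-frequency
#'   texture (default 4).
#' @param illum_level_range `c(l_min, l_max)` in `(0, 1]`: the smooth
#'   illumination field is rescaled to this range (default `c(0.1, 0.35)`,
#'   i.e. deep dusk).
#' @param illum_smoothness Gaussian-blur bandwidth (pixels) of the
#'   illumination field (default 12).
#' @param noise_std Additive Gaussian sensor-noise sigma in intensity units
#'   (default 0.01).
#' @param channel_tint If `TRUE`, apply a mild per-channel illumination tint;
#'   default `FALSE` (gray illumination, the standard Retinex assumption).
#' @param seed Integer seed; scenes are reproducible bit-for-bit.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height = 64L, width = 64L, n_shapes = 3L,
                       background_texture_scale = 4, illum_level_range = c(0.1, 0.35),
                       illum_smoothness = 12, noise_std = 0.01,
                       channel_tint = FALSE, seed = 0L) {
  height <- as.integer(height); width <- as.integer(width)
  background_texture_scale <- as.numeric(background_texture_scale)
  illum_level_range <- as.numeric(illum_level_range)
  illum_smoothness <- as.numeric(illum_smoothness)
  noise_std <- as.numeric(noise_std)
  if (height < 8L || width < 8L) {
    scretinex_error("scene_spec: dimensions must be >= 8", "scretinex_config")
  }
  l <- illum_level_range
  if (length(l) != 2L || l[1] <= 0 || l[1] > l[2] || l[2] > 1) {
    scretinex_error("scene_spec: need 0 < l_min <= l_max <= 1", "scretinex_config")
  }
  if (noise_std < 0) {
    scretinex_error("scene_spec: noise_std must be >= 0", "scretinex_config")
  }
  structure(
    list(height = height, width = width, n_shapes = as.integer(n_shapes),
         background_texture_scale = background_texture_scale,
         illum_level_range = l, illum_smoothness = illum_smoothness,
         noise_std = noise_std, channel_tint = isTRUE(channel_tint),
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# separable Gaussian blur with replicate edges
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(h, r), , drop = FALSE])
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + h - 1L), , drop = FALSE]
  mp <- cbind(out[, rep(1L, r), drop = FALSE], out, out[, rep(w, r), drop = FALSE])
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * mp[, i:(i + w - 1L), drop = FALSE]
  out
}

rescale_to <- function(m, lo, hi) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Generate one synthetic low-light scene
#'
#' @param spec A [scene_spec()].
#' @return An object of class `synthetic_triple`: `reflectance_gt`
#'   (`H x W x 3` in `[0, 1]`), `illumination_gt` (`H x W` matrix in
#'   `[l_min, l_max]`, shared across channels unless tinted) and
#'   `observation` (`clip(reflectance * illumination + noise, 0, 1)`).  With
#'   `noise_std = 0` the observation equals the product exactly (the clip is
#'   inactive because both factors are at most 1).
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width

  # textured background reflectance
  base <- gaussian_blur(matrix(stats::runif(h * w), h, w),
                        spec$background_texture_scale)
  base <- rescale_to(base, 0.15, 0.55)
  refl <- array(0, dim = c(h, w, 3L))
  gains <- stats::runif(3L, 0.9, 1.1)
  for (ch in 1:3) refl[, , ch] <- pmin(base * gains[ch], 1)

  # bright elliptical bodies with distinct mean intensities
  if (spec$n_shapes > 0L) {
    levels <- seq(0.6, 0.95, length.out = spec$n_shapes)[sample.int(spec$n_shapes)]
    ys <- matrix(rep(seq_len(h), w), h, w)
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    for (s in seq_len(spec$n_shapes)) {
      cy <- stats::runif(1, 0.2, 0.8) * h
      cx <- stats::runif(1, 0.2, 0.8) * w
      ay <- stats::runif(1, 0.10, 0.25) * h
      ax <- stats::runif(1, 0.10, 0.25) * w
      th <- stats::runif(1, 0, pi)
      dy <- ys - cy; dx <- xs - cx
      ry <- cos(th) * dy - sin(th) * dx
      rx <- sin(th) * dy + cos(th) * dx
      inside <- (ry / ay)^2 + (rx / ax)^2 <= 1
      tint <- stats::runif(3L, 0.92, 1)
      for (ch in 1:3) {
        plane <- refl[, , ch]
        plane[inside] <- pmin(levels[s] * tint[ch], 1)
        refl[, , ch] <- plane
      }
    }
  }

  # smooth illumination field
  illum <- gaussian_blur(matrix(stats::runif(h * w), h, w), spec$illum_smoothness)
  illum <- rescale_to(illum, spec$illum_level_range[1], spec$illum_level_range[2])

  tint <- if (spec$channel_tint) stats::runif(3L, 0.9, 1) else rep(1, 3L)
  obs <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) obs[, , ch] <- refl[, , ch] * illum * tint[ch]
  if (spec$noise_std > 0) {
    obs <- obs + array(stats::rnorm(h * w * 3L, sd = spec$noise_std), dim = dim(obs))
    obs <- pmin(pmax(obs, 0), 1)
  }

  structure(list(reflectance_gt = refl, illumination_gt = illum,
                 observation = obs, spec = spec, seed = spec$seed),
            class = "synthetic_triple")
}

#' Generate a reproducible set of synthetic scenes
#'
#' Scene `i` uses seed `base_seed + i - 1`.  When `dir` is given, the
#' observations are written as 8-bit PNG, the ground-truth fields as
#' 16-bit TIFF, and a JSON manifest records the spec and per-item seeds so
#' the set can be regenerated bit-for-bit from the manifest alone
#' (regeneration, not the quantised files, is the lossless path).
#'
#' @param n Number of scenes (>= 1).
#' @param spec A [scene_spec()]; its `seed` field is overridden per item.
#' @param base_seed First seed of the sequence.
#' @param dir Optional output directory.
#' @return List of `synthetic_triple`s; when `dir` is given, the manifest
#'   path is attached as attribute `"manifest"`.
#' @export
make_fixture_set <- function(n, spec, base_seed = 0L, dir = NULL) {
  stopifnot(n >= 1L, inherits(spec, "scene_spec"))
  seeds <- as.integer(base_seed) + seq_len(n) - 1L
  triples <- lapply(seeds, function(s) {
    sp <- spec
    sp$seed <- s
    make_scene(sp)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    items <- vector("list", n)
    for (i in seq_len(n)) {
      obs_file <- sprintf("obs_%03d.png", i)
      refl_file <- sprintf("reflectance_gt_%03d.tif", i)
      illum_file <- sprintf("illumination_gt_%03d.tif", i)
      write_image(triples[[i]]$observation, file.path(dir, obs_file))
      write_gt16(triples[[i]]$reflectance_gt, file.path(dir, refl_file))
      write_gt16(triples[[i]]$illumination_gt, file.path(dir, illum_file))
      items[[i]] <- list(index = i, seed = seeds[i], observation = obs_file,
                         reflectance_gt = refl_file, illumination_gt = illum_file)
    }
    manifest <- list(format = "sadp-fixture-manifest", version = 1L,
                     n = n, base_seed = as.integer(base_seed),
                     spec = unclass(spec)[setdiff(names(spec), "seed")],
                     items = items)
    mpath <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    attr(triples, "manifest") <- mpath
  }
  triples
}

#' Regenerate a fixture set from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [make_fixture_set()].
#' @return List of `synthetic_triple`s, bitwise-identical to the originals.
#' @export
read_fixture_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    scretinex_error(sprintf("manifest '%s' not found", manifest_path), "scretinex_io")
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(m$format, "sadp-fixture-manifest")) {
    scretinex_error(sprintf("'%s' is not a fixture manifest", manifest_path),
                    "scretinex_corrupt")
  }
  sp <- m$spec
  spec <- scene_spec(height = sp$height, width = sp$width, n_shapes = sp$n_shapes,
                     background_texture_scale = sp$background_texture_scale,
                     illum_level_range = sp$illum_level_range,
                     illum_smoothness = sp$illum_smoothness,
                     noise_std = sp$noise_std, channel_tint = sp$channel_tint)
  make_fixture_set(m$n, spec, base_seed = m$base_seed)
}
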