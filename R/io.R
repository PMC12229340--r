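# Image I/O: everything enters the package as an H x W x 3 double array in
# [0, 1] (row-major, origin top-left) and leaves as 8-bit PNG/JPEG/TIFF.

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Read an image as a float RGB field
#'
#' Supports PNG, JPEG and TIFF, 8- or 16-bit, 1 or 3 channels.  Grayscale is
#' replicated to 3 channels; an alpha channel is dropped.
#'
#' @param path Path to the image file.
#' @return `H x W x 3` double array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    scretinex_error(sprintf("cannot read image '%s': file not found", path),
                    "scretinex_io")
  }
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = {
        if (!requireNamespace("jpeg", quietly = TRUE)) {
          scretinex_error(sprintf("cannot read '%s': the jpeg package is not installed", path),
                          "scretinex_io")
        }
        jpeg::readJPEG(path)
      },
      tif = ,
      tiff = {
        if (!requireNamespace("tiff", quietly = TRUE)) {
          scretinex_error(sprintf("cannot read '%s': the tiff package is not installed", path),
                          "scretinex_io")
        }
        tiff::readTIFF(path)
      },
      scretinex_error(sprintf("cannot read image '%s': unsupported extension '%s'",
                              path, ext), "scretinex_io")
    ),
    error = function(e) {
      if (inherits(e, "scretinex_error")) stop(e)
      scretinex_error(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
                      "scretinex_io")
    }
  )
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  nc <- dim(img)[3]
  if (nc == 1L) {
    img <- array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
  } else if (nc >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else {
    scretinex_error(sprintf("cannot read image '%s': %d channels unsupported", path, nc),
                    "scretinex_io")
  }
  clip01(img)
}

#' Write an image as 8-bit PNG (or JPEG/TIFF by extension)
#'
#' Values are clipped to `[0, 1]`, scaled by 255 and rounded half away from
#' zero.  For PNG, a write/read round trip differs from `clip01(x)` by at
#' most 1/255 per pixel.
#'
#' @param img `H x W x 3` (or `H x W`) numeric array; any real values.
#' @param path Output path; format chosen by extension.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  q <- floor(clip01(img) * 255 + 0.5) / 255
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
      png = png::writePNG(q, path),
      jpg = ,
      jpeg = jpeg::writeJPEG(q, path, quality = 0.95),
      tif = ,
      tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
      scretinex_error(sprintf("cannot write '%s': unsupported extension '%s'",
                              path, ext), "scretinex_io")
    )
    TRUE
  }, error = function(e) {
    if (inherits(e, "scretinex_error")) stop(e)
    scretinex_error(sprintf("cannot write image '%s': %s", path, conditionMessage(e)),
                    "scretinex_io")
  })
  invisible(path)
}

# 16-bit TIFF for ground-truth fields
write_gt16 <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    return(invisible(NULL))
  }
  tiff::writeTIFF(clip01(img), path, bits.per.sample = 16L)
  invisible(path)
}

# 2x downscale by mean-pooling (odd trailing row/column cropped)
downsample_half <- function(img) {
  h <- dim(img)[1] %/% 2L * 2L
  w <- dim(img)[2] %/% 2L * 2L
  out <- array(0, dim = c(h %/% 2L, w %/% 2L, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    m <- img[1:h, 1:w, ch]
    out[, , ch] <- (m[seq(1L, h, 2L), seq(1L, w, 2L)] +
                    m[seq(2L, h, 2L), seq(1L, w, 2L)] +
                    m[seq(1L, h, 2L), seq(2L, w, 2L)] +
                    m[seq(2L, h, 2L), seq(2L, w, 2L)]) / 4
  }
  out
}
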