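# Fixed (non-trainable) feature extractor for the perceptual loss.
#
# The reference choice in the literature is a pretrained VGG; shipping one is
# neither possible offline nor necessary for the loss to do its job, which
# only requires a fixed, deterministic multi-scale feature map.  The default
# here is a 3-layer seeded-random convolutional stack — random convolutional
# features are a long-standing baseline for perceptual similarity — and the
# extractor is pluggable so a pretrained stack can be supplied where
# available.

#' Fixed feature extractor for the perceptual loss
#'
#' @param kind `"random"` (3 fixed seeded-random 3x3 conv layers,
#'   3 -> 8 -> 8 -> 8 channels, ReLU between layers) or `"identity"` (the
#'   features are the pixels themselves, making the perceptual loss collapse
#'   onto the fidelity loss — useful for testing).
#' @param seed Seed for the random stack (default 42); two extractors built
#'   with the same seed are identical.
#' @param channels Feature channels of the random stack (default 8).
#' @return An object of class `feature_extractor` with a `provenance`
#'   descriptor (`"seeded-random"` or `"identity"`).
#' @export
feature_extractor <- function(kind = c("random", "identity"), seed = 42L,
                              channels = 8L) {
  kind <- match.arg(kind)
  if (kind == "identity") {
    return(structure(list(kind = "identity", provenance = "identity",
                          layers = list()),
                     class = "feature_extractor"))
  }
  channels <- as.integer(channels)
  k <- 3L
  set.seed(as.integer(seed))
  conv_par <- function(c_in, c_out) {
    fan <- k * k * c_in
    list(W = matrix(stats::rnorm(fan * c_out, sd = sqrt(2 / fan)), nrow = fan),
         b = numeric(c_out))
  }
  layers <- list(
    list(par = conv_par(3L, channels), act = "relu"),
    list(par = conv_par(channels, channels), act = "relu"),
    list(par = conv_par(channels, channels), act = "linear")
  )
  structure(list(kind = "random", provenance = "seeded-random", seed = seed,
                 kernel = k, layers = layers),
            class = "feature_extractor")
}

feat_forward <- function(V, t) {
  if (V$kind == "identity") {
    return(list(out = t, cache = list()))
  }
  cache <- vector("list", length(V$layers))
  h <- t
  for (i in seq_along(V$layers)) {
    ly <- V$layers[[i]]
    cv <- conv_forward(h, ly$par$W, ly$par$b, V$kernel)
    if (ly$act == "relu") {
      rl <- relu_forward(cv$out)
      cache[[i]] <- list(conv = cv$cache, relu = rl$cache)
      h <- rl$out
    } else {
      cache[[i]] <- list(conv = cv$cache, relu = NULL)
      h <- cv$out
    }
  }
  list(out = h, cache = cache)
}

# gradient with respect to the input only; extractor weights are fixed
feat_backward <- function(V, cache, gy) {
  if (V$kind == "identity") return(gy)
  g <- gy
  for (i in rev(seq_along(V$layers))) {
    if (!is.null(cache[[i]]$relu)) g <- relu_backward(g, cache[[i]]$relu)
    g <- conv_backward(g, cache[[i]]$conv, V$layers[[i]]$par$W)$gx
  }
  g
}
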