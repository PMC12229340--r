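# Unsupervised training: joint Adam optimisation of IE-Net and SCA-Net
# against the four-term loss on T-stage traces of unlabeled low-light
# images.  Fully deterministic given the seed.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with `beta1 = 0.9`,
#' `beta2 = 0.999`, `eps = 1e-8`, learning rate `1e-4`, batch size 2,
#' `T = 3` stages, 100 epochs, loss weights `alpha = 1`, `beta = 1.5`.
#'
#' @param learning_rate Adam step size (default `1e-4`).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and
#'   stabiliser.
#' @param batch_size Images per optimisation step (default 2).
#' @param epochs Number of passes over the data (default 100; `0` is allowed
#'   and returns the initialisation untouched).
#' @param stages Cascade depth T during training (default 3).
#' @param alpha,beta,sigma,window Loss weighting, see [loss_weights()].
#' @param seed Run seed: initialises the weights and drives the shuffling.
#' @param use_sca Apply the self-calibration module (default `TRUE`);
#'   `FALSE` trains the literal illumination cascade, the ablation
#'   configuration.
#' @param grad_clip Optional gradient-norm clip (default `Inf`, i.e. off).
#' @param ienet_spec,scanet_spec Architecture overrides.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8,
                         batch_size = 2L, epochs = 100L, stages = 3L,
                         alpha = 1, beta = 1.5, sigma = 0.1, window = 2L,
                         seed = 0L, use_sca = TRUE, grad_clip = Inf,
                         ienet_spec = network_spec("ienet"),
                         scanet_spec = network_spec("scanet")) {
  if (learning_rate <= 0 || adam_beta1 <= 0 || adam_beta2 <= 0 || adam_eps <= 0) {
    scretinex_error("train_config: optimizer constants must be positive",
                    "scretinex_config")
  }
  if (batch_size < 1L || epochs < 0L || stages < 1L) {
    scretinex_error("train_config: batch_size >= 1, epochs >= 0, stages >= 1",
                    "scretinex_config")
  }
  structure(
    list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
         adam_beta2 = adam_beta2, adam_eps = adam_eps,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         stages = as.integer(stages),
         weights = loss_weights(alpha, beta, sigma, window),
         seed = as.integer(seed), use_sca = isTRUE(use_sca),
         grad_clip = grad_clip,
         ienet_spec = ienet_spec, scanet_spec = scanet_spec),
    class = "train_config"
  )
}

config_snapshot <- function(cfg) {
  list(learning_rate = cfg$learning_rate, adam_beta1 = cfg$adam_beta1,
       adam_beta2 = cfg$adam_beta2, adam_eps = cfg$adam_eps,
       batch_size = cfg$batch_size, epochs = cfg$epochs, stages = cfg$stages,
       alpha = cfg$weights$alpha, beta = cfg$weights$beta,
       sigma = cfg$weights$sigma, window = cfg$weights$window,
       seed = cfg$seed, use_sca = cfg$use_sca, grad_clip = cfg$grad_clip)
}

#' Read a training configuration from a YAML key-value file
#'
#' Recognised keys mirror the [train_config()] arguments; unknown keys are
#' rejected rather than silently ignored.
#'
#' @param path Path to a YAML file.
#' @return A `train_config`.
#' @export
read_train_config <- function(path) {
  if (!file.exists(path)) {
    scretinex_error(sprintf("config file '%s' not found", path), "scretinex_io")
  }
  kv <- yaml::read_yaml(path)
  allowed <- c("learning_rate", "adam_beta1", "adam_beta2", "adam_eps",
               "batch_size", "epochs", "stages", "alpha", "beta", "sigma",
               "window", "seed", "use_sca", "grad_clip")
  unknown <- setdiff(names(kv), allowed)
  if (length(unknown) > 0L) {
    scretinex_error(sprintf("config file '%s' has unknown keys: %s",
                            path, paste(unknown, collapse = ", ")),
                    "scretinex_config")
  }
  do.call(train_config, kv)
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, cfg) {
  state$t <- state$t + 1L
  state$m <- cfg$adam_beta1 * state$m + (1 - cfg$adam_beta1) * grad
  state$v <- cfg$adam_beta2 * state$v + (1 - cfg$adam_beta2) * grad^2
  mhat <- state$m / (1 - cfg$adam_beta1^state$t)
  vhat <- state$v / (1 - cfg$adam_beta2^state$t)
  theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + cfg$adam_eps)
  list(state = state, theta = theta)
}

set_net_params <- function(net, flat) {
  net$params <- unflatten_params(flat, net$params)
  net
}

#' Train the enhancement networks
#'
#' Joint unsupervised optimisation of IE-Net (and SCA-Net, unless
#' `use_sca = FALSE`) with Adam against the total loss on `stages`-stage
#' traces.  Batch-norm uses batch statistics during training and updates its
#' running statistics, which the emitted checkpoints freeze for inference.
#' Deterministic: the seed fixes the weight initialisation and the epoch
#' shuffling, so identical configs give bitwise-identical checkpoints on one
#' platform.
#'
#' @param config A [train_config()].
#' @param images List of `H x W x 3` arrays in `[0, 1]` (unlabeled low-light
#'   images; within a batch all images must share one size).
#' @param V A [feature_extractor()] for the perceptual term.
#' @return A list with `checkpoint` (final), `best_checkpoint` (lowest
#'   epoch-mean total loss) and `log` (data.frame, one row per epoch:
#'   loss-term means and mean stage divergence).
#' @export
sadp_train <- function(config, images, V = feature_extractor("random")) {
  stopifnot(inherits(config, "train_config"))
  if (!is.list(images) || length(images) == 0L) {
    scretinex_error("sadp_train needs a non-empty list of images", "scretinex_input")
  }
  lapply(images, check_image, arg = "images[[i]]")

  set.seed(config$seed)
  ienet <- build_network(config$ienet_spec, seed = config$seed)
  scanet <- build_network(config$scanet_spec, seed = config$seed + 1L)

  theta <- flatten_params(ienet$params)
  vartheta <- flatten_params(scanet$params)
  opt_ie <- adam_state(length(theta))
  opt_sc <- adam_state(length(vartheta))

  n_img <- length(images)
  log_rows <- vector("list", config$epochs)
  best <- list(loss = Inf, ckpt = NULL)

  for (epoch in seq_len(config$epochs)) {
    order <- sample.int(n_img)
    batch_starts <- seq(1L, n_img, by = config$batch_size)
    ep_break <- c(l_f = 0, l_s = 0, l_sem = 0, l_grad = 0, total = 0)
    ep_div <- 0
    n_div <- 0L

    for (bs in batch_starts) {
      idx <- order[bs:min(bs + config$batch_size - 1L, n_img)]
      batch <- images[idx]
      lg <- loss_and_grad(batch, ienet, scanet, config$stages,
                          config$weights, V, use_sca = config$use_sca,
                          training = TRUE, want_grad = TRUE)
      if (!is.finite(lg$breakdown$total)) {
        scretinex_error(sprintf(
          "non-finite loss at epoch %d (f=%.3g s=%.3g sem=%.3g grad=%.3g); aborting",
          epoch, lg$breakdown$l_f, lg$breakdown$l_s, lg$breakdown$l_sem,
          lg$breakdown$l_grad), "scretinex_numeric")
      }
      ienet <- lg$ienet
      scanet <- lg$scanet

      g_theta <- lg$g_theta
      if (is.finite(config$grad_clip)) {
        nrm <- sqrt(sum(g_theta^2))
        if (nrm > config$grad_clip) g_theta <- g_theta * config$grad_clip / nrm
      }
      stepped <- adam_step(opt_ie, theta, g_theta, config)
      opt_ie <- stepped$state
      theta <- stepped$theta
      ienet <- set_net_params(ienet, theta)

      if (config$use_sca) {
        g_var <- lg$g_vartheta
        if (is.finite(config$grad_clip)) {
          nrm <- sqrt(sum(g_var^2))
          if (nrm > config$grad_clip) g_var <- g_var * config$grad_clip / nrm
        }
        stepped <- adam_step(opt_sc, vartheta, g_var, config)
        opt_sc <- stepped$state
        vartheta <- stepped$theta
        scanet <- set_net_params(scanet, vartheta)
      }

      for (nm in names(ep_break)) {
        ep_break[[nm]] <- ep_break[[nm]] + lg$breakdown[[nm]] * length(idx)
      }
      if (config$stages >= 2L) {
        fw <- lg$fw
        a1 <- fw$stages[[1L]]$a$x
        aT <- fw$stages[[fw$T]]$a$x
        ep_div <- ep_div + mean((a1 - aT)^2) * length(idx)
        n_div <- n_div + length(idx)
      }
    }

    ep_break <- ep_break / n_img
    row <- data.frame(epoch = epoch, l_f = ep_break[["l_f"]],
                      l_s = ep_break[["l_s"]], l_sem = ep_break[["l_sem"]],
                      l_grad = ep_break[["l_grad"]], total = ep_break[["total"]],
                      stage_divergence = if (n_div > 0L) ep_div / n_div else NA_real_)
    log_rows[[epoch]] <- row
    if (ep_break[["total"]] < best$loss) {
      best <- list(loss = ep_break[["total"]],
                   ckpt = make_checkpoint(ienet, scanet,
                                          config_snapshot(config), config$seed))
    }
  }

  ckpt <- make_checkpoint(ienet, scanet, config_snapshot(config), config$seed)
  if (is.null(best$ckpt)) best$ckpt <- ckpt
  list(checkpoint = ckpt, best_checkpoint = best$ckpt,
       log = if (config$epochs > 0L) do.call(rbind, log_rows) else
         data.frame(epoch = integer(), l_f = numeric(), l_s = numeric(),
                    l_sem = numeric(), l_grad = numeric(), total = numeric(),
                    stage_divergence = numeric()))
}

#' Evaluate a checkpoint on a set of images without weight updates
#'
#' Inference mode throughout (frozen batch-norm statistics).  Returns the
#' mean loss breakdown over the images and the mean stage divergence between
#' the first and last enhanced outputs (empty when `T = 1`).
#'
#' @param ckpt An `sadp_checkpoint`.
#' @param images List of `H x W x 3` arrays in `[0, 1]`.
#' @param T Number of stages to unroll.
#' @param weights A [loss_weights()].
#' @param V A [feature_extractor()].
#' @param use_sca Apply self-calibration between stages; defaults to the
#'   checkpoint's training setting (or `TRUE`).
#' @return A list with `breakdown` (mean `loss_breakdown`) and
#'   `stage_divergence` (scalar mean of `a_1` vs `a_T`, `NA` when `T = 1`).
#' @export
evaluate_epoch <- function(ckpt, images, T = 3L, weights = loss_weights(),
                           V = feature_extractor("random"), use_sca = NULL) {
  stopifnot(inherits(ckpt, "sadp_checkpoint"))
  if (is.null(use_sca)) {
    use_sca <- if (!is.null(ckpt$train_config$use_sca)) ckpt$train_config$use_sca else TRUE
  }
  nets <- checkpoint_networks(ckpt)
  acc <- c(l_f = 0, l_s = 0, l_sem = 0, l_grad = 0, total = 0)
  div <- 0
  for (img in images) {
    check_image(img)
    lg <- loss_and_grad(list(img), nets$ienet, nets$scanet, T, weights, V,
                        use_sca = use_sca, training = FALSE, want_grad = FALSE)
    for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + lg$breakdown[[nm]]
    if (T >= 2L) {
      div <- div + mean((lg$fw$stages[[1L]]$a$x - lg$fw$stages[[T]]$a$x)^2)
    }
  }
  n <- length(images)
  br <- as.list(acc / n)
  list(breakdown = structure(br, class = "loss_breakdown"),
       stage_divergence = if (T >= 2L) div / n else NA_real_)
}
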