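# Reverse-mode gradients of the total loss with respect to the shared
# IE-Net parameters (theta) and SCA-Net parameters (vartheta).
#
# Forward graph per stage t (v_1 = c):
#   u_t = H_theta(v_t);  b_t = clamp(v_t + u_t, eps, 1);  a_t = c / b_t
#   d_t = phi_vartheta(a_t);  v_{t+1} = c + d_t          (self-calibrated)
#   v_{t+1} = b_t                                        (ablation cascade)
#
# The loss touches b_t and v_t (fidelity, smoothness, perceptual) and a_t
# (gradient term); a_t also feeds the next stage through d_t, so the reverse
# sweep walks stages from T down to 1 carrying the gradient of v_{t+1}.
# Weight sharing means the per-stage parameter gradients simply accumulate.

grads_zero_like <- function(net) numeric(length(flatten_params(net$params)))

# Per-stage loss values and direct gradients on (b, v, a), computed on the
# stacked batch tensors.  Losses are means over batch elements, so the
# stacked mean equals the batch-average of per-image means.
batch_loss_terms <- function(fw, weights, V, want_grad = TRUE) {
  T <- fw$T
  n <- fw$c$n
  h <- fw$c$h; w <- fw$c$w
  l_f <- l_s <- l_sem <- l_grad <- 0
  stage_grads <- vector("list", T)
  for (t in seq_len(T)) {
    st <- fw$stages[[t]]
    gb <- gv <- ga <- if (want_grad) matrix(0, nrow(st$b$x), ncol(st$b$x)) else NULL

    # the loss anchor is the corrected input c + d_{t-1}; with the
    # calibration bypassed d is identically zero, so every stage anchors to
    # the raw observation (a constant: no gradient flows through it)
    anchor <- if (fw$use_sca) st$v else fw$c

    # fidelity on the stacked matrix
    diff <- st$b$x - anchor$x
    l_f <- l_f + mean(diff^2)
    if (want_grad) {
      g <- 2 * diff / length(diff)
      gb <- gb + weights$alpha * g
      gv <- gv - weights$alpha * g
    }

    # perceptual on the stacked batch (no cross-image coupling in the convs)
    fb <- feat_forward(V, st$b)
    fv <- feat_forward(V, anchor)
    fdiff <- fb$out$x - fv$out$x
    l_sem <- l_sem + mean(fdiff^2)
    if (want_grad) {
      gf <- 2 * fdiff / length(fdiff)
      gfb <- feat_backward(V, fb$cache, new_tensor(gf, n, h, w))
      gfv <- feat_backward(V, fv$cache, new_tensor(-gf, n, h, w))
      gb <- gb + gfb$x
      gv <- gv + gfv$x
    }

    # smoothness and gradient terms are spatial: loop over batch images
    for (i in seq_len(n)) {
      rows <- tensor_rows(st$b, i)
      b_img <- array(st$b$x[rows, ], dim = c(h, w, 3L))
      v_img <- array(anchor$x[rows, ], dim = c(h, w, 3L))
      a_img <- array(st$a$x[rows, ], dim = c(h, w, 3L))
      sm <- smoothness_term(b_img, v_img, weights$sigma, weights$window, want_grad)
      gr <- gradient_term(a_img, want_grad)
      l_s <- l_s + sm$val / n
      l_grad <- l_grad + gr$val / n
      if (want_grad) {
        gb[rows, ] <- gb[rows, ] + weights$beta * matrix(sm$gb, ncol = 3L) / n
        gv[rows, ] <- gv[rows, ] + weights$beta * matrix(sm$gv, ncol = 3L) / n
        ga[rows, ] <- ga[rows, ] + matrix(gr$ga, ncol = 3L) / n
      }
    }
    if (want_grad) {
      if (!fw$use_sca) gv[] <- 0   # constant anchor: no gradient through it
      stage_grads[[t]] <- list(gb = gb, gv = gv, ga = ga)
    }
  }
  breakdown <- list(l_f = l_f, l_s = l_s, l_sem = l_sem, l_grad = l_grad)
  breakdown$total <- weights$alpha * l_f + weights$beta * l_s + l_sem + l_grad
  list(breakdown = structure(breakdown, class = "loss_breakdown"),
       stage_grads = stage_grads)
}

# Reverse sweep through the cascade.  Returns flat gradient vectors aligned
# with flatten_params() of each network.
engine_backward <- function(fw, ienet, scanet, stage_grads) {
  n <- fw$c$n; h <- fw$c$h; w <- fw$c$w
  g_theta <- grads_zero_like(ienet)
  g_vartheta <- if (fw$use_sca) grads_zero_like(scanet) else numeric(0)
  gv_next <- NULL

  for (t in rev(seq_len(fw$T))) {
    st <- fw$stages[[t]]
    ga <- stage_grads[[t]]$ga
    gb <- stage_grads[[t]]$gb

    if (!is.null(gv_next)) {
      if (fw$use_sca) {
        # v_{t+1} = c + phi(a_t): route gv_next through SCA-Net into a_t
        nb <- net_backward(scanet, st$sc_cache, new_tensor(gv_next, n, h, w))
        g_vartheta <- g_vartheta + flatten_params(nb$grads)
        ga <- ga + nb$gx$x
      } else {
        # v_{t+1} = b_t
        gb <- gb + gv_next
      }
    }

    # a = c / b  =>  dL/db += ga * (-c / b^2)
    gb <- gb - ga * fw$c$x / (st$b$x^2)

    # b = clamp(v + u): gradient passes only where the clamp was inactive
    gs <- gb * st$mask

    ib <- net_backward(ienet, st$ie_cache, new_tensor(gs, n, h, w))
    g_theta <- g_theta + flatten_params(ib$grads)

    gv_next <- gs + ib$gx$x + stage_grads[[t]]$gv
  }
  list(g_theta = g_theta, g_vartheta = g_vartheta)
}

# One full forward + loss + backward on a batch of images (list of H x W x 3
# arrays).  Returns the loss breakdown, flat gradients and networks with
# updated batch-norm running statistics.
loss_and_grad <- function(images, ienet, scanet, T, weights, V,
                          use_sca = TRUE, training = TRUE, want_grad = TRUE) {
  cs <- tensor_from_images(images)
  fw <- forward_trace(cs, ienet, scanet, T, training = training,
                      use_sca = use_sca, final_d = FALSE)
  lt <- batch_loss_terms(fw, weights, V, want_grad = want_grad)
  out <- list(breakdown = lt$breakdown, ienet = fw$ienet, scanet = fw$scanet,
              fw = fw)
  if (want_grad) {
    out[c("g_theta", "g_vartheta")] <-
      engine_backward(fw, fw$ienet, fw$scanet, lt$stage_grads)
  }
  out
}
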