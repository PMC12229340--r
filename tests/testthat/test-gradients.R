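# Analytic reverse-mode gradients against central finite differences.
# Exactness here underwrites every training result in the package.

test_that("network parameter and input gradients match finite differences", {
  ns <- asNamespace("scretinex")
  net <- build_network(network_spec("scanet", hidden_channels = 4L,
                                    n_blocks = 2L), seed = 2)
  set.seed(3)
  t0 <- ns$tensor_from_images(list(random_image(6, 5, 0, 0.8),
                                   random_image(6, 5, 0, 0.8)))
  loss_of <- function(n, training) mean(ns$net_forward(n, t0, training)$out$x^2)

  for (training in c(TRUE, FALSE)) {
    fw <- ns$net_forward(net, t0, training)
    gy <- ns$new_tensor(2 * fw$out$x / length(fw$out$x), t0$n, t0$h, t0$w)
    nb <- ns$net_backward(net, fw$cache, gy)
    analytic <- ns$flatten_params(nb$grads)
    theta <- ns$flatten_params(net$params)
    eps <- 1e-6
    set.seed(7)
    for (i in sample(length(theta), 30)) {
      tp <- theta
      tp[i] <- theta[i] + eps
      up <- loss_of(ns$set_net_params(net, tp), training)
      tp[i] <- theta[i] - eps
      dn <- loss_of(ns$set_net_params(net, tp), training)
      expect_equal(analytic[i], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
    # input gradient
    for (i in sample(length(t0$x), 15)) {
      xp <- t0$x
      xp[i] <- t0$x[i] + eps
      up <- loss_of_x <- mean(ns$net_forward(net, ns$new_tensor(xp, t0$n, t0$h, t0$w), training)$out$x^2)
      xp[i] <- t0$x[i] - eps
      dn <- mean(ns$net_forward(net, ns$new_tensor(xp, t0$n, t0$h, t0$w), training)$out$x^2)
      expect_equal(nb$gx$x[i], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("full training-loss gradients match finite differences in all modes", {
  ns <- asNamespace("scretinex")
  ie <- build_network(network_spec("ienet"), seed = 1)
  sc <- build_network(network_spec("scanet", hidden_channels = 4L,
                                   n_blocks = 2L), seed = 2)
  set.seed(3)
  imgs <- list(random_image(6, 5, 0, 0.5), random_image(6, 5, 0, 0.5))
  w <- loss_weights()
  V <- feature_extractor("random", channels = 4L)
  theta <- ns$flatten_params(ie$params)
  vartheta <- ns$flatten_params(sc$params)
  eps <- 1e-6

  for (T in c(1L, 3L)) {
    for (sca in c(TRUE, FALSE)) {
      lg <- ns$loss_and_grad(imgs, ie, sc, T, w, V, use_sca = sca,
                             training = TRUE, want_grad = TRUE)
      total_of <- function(ienet, scanet) {
        ns$loss_and_grad(imgs, ienet, scanet, T, w, V, use_sca = sca,
                         training = TRUE, want_grad = FALSE)$breakdown$total
      }
      set.seed(100 + T)
      for (i in sample(length(theta), 12)) {
        tp <- theta
        tp[i] <- theta[i] + eps
        up <- total_of(ns$set_net_params(ie, tp), sc)
        tp[i] <- theta[i] - eps
        dn <- total_of(ns$set_net_params(ie, tp), sc)
        expect_equal(lg$g_theta[i], (up - dn) / (2 * eps), tolerance = 1e-3)
      }
      if (sca && T > 1L) {
        for (i in sample(length(vartheta), 12)) {
          vp <- vartheta
          vp[i] <- vartheta[i] + eps
          up <- total_of(ie, ns$set_net_params(sc, vp))
          vp[i] <- vartheta[i] - eps
          dn <- total_of(ie, ns$set_net_params(sc, vp))
          expect_equal(lg$g_vartheta[i], (up - dn) / (2 * eps), tolerance = 1e-3)
        }
      }
    }
  }
})

test_that("loss-term array gradients match finite differences", {
  ns <- asNamespace("scretinex")
  set.seed(4)
  b <- random_image(6, 5, 0.2, 0.9)
  v <- random_image(6, 5, 0, 1.4)
  a <- random_image(6, 5, 0, 1.2)
  eps <- 1e-6
  check_arr <- function(value_of, x, gx, n = 20) {
    idx <- sample(length(x), n)
    for (i in idx) {
      xp <- x
      xp[i] <- x[i] + eps
      up <- value_of(xp)
      xp[i] <- x[i] - eps
      dn <- value_of(xp)
      expect_equal(gx[i], (up - dn) / (2 * eps), tolerance = 1e-5)
    }
  }
  sm <- ns$smoothness_term(b, v, 0.1, 2L, want_grad = TRUE)
  check_arr(function(bb) ns$smoothness_term(bb, v, 0.1, 2L)$val, b, sm$gb)
  check_arr(function(vv) ns$smoothness_term(b, vv, 0.1, 2L)$val, v, sm$gv)
  gr <- ns$gradient_term(a, want_grad = TRUE)
  check_arr(function(aa) ns$gradient_term(aa)$val, a, gr$ga)
  fi <- ns$fidelity_term(b, v, want_grad = TRUE)
  check_arr(function(bb) ns$fidelity_term(bb, v)$val, b, fi$gb)
})
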