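# The desk-scale evaluation protocol shared by the acceptance checks:
# 20 synthetic 64x64 scenes (seeds 100..119) for training, 6 held-out
# scenes (seeds 500..505), paired 50-epoch runs (seed 7, T = 3, batch 2)
# with and without the self-calibration module, learning rate 5e-4 (the
# desk-scale step size; see the methods vignette).  Runs are cached so the
# training cost is paid once per test session.

protocol_spec <- function() scene_spec(seed = 0L)

protocol_config <- function(use_sca = TRUE) {
  train_config(epochs = 50L, seed = 7L, learning_rate = 5e-4,
               use_sca = use_sca)
}

.protocol_cache <- new.env(parent = emptyenv())

protocol_runs <- function() {
  if (is.null(.protocol_cache$runs)) {
    train_triples <- make_fixture_set(20, protocol_spec(), base_seed = 100)
    held_triples <- make_fixture_set(6, protocol_spec(), base_seed = 500)
    imgs <- lapply(train_triples, `[[`, "observation")
    fit_sca <- sadp_train(protocol_config(TRUE), imgs)
    fit_nosca <- sadp_train(protocol_config(FALSE), imgs)
    .protocol_cache$runs <- list(
      train_triples = train_triples, held_triples = held_triples,
      train_images = imgs, fit_sca = fit_sca, fit_nosca = fit_nosca
    )
  }
  .protocol_cache$runs
}
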