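# Shared fixture builders. Everything is generated in code at test time.

# A sleep_net with unit scales and the given weights/thresholds, bypassing
# the data-based normalisation (for hand-traced dynamics tests).
manual_sleep_net <- function(weights, thresholds) {
  layer_sizes <- c(ncol(weights[[1L]]), vapply(weights, nrow, integer(1)))
  net <- structure(list(layer_sizes = layer_sizes, weights = weights,
                        mode = "wake"), class = "dense_net")
  ref <- list(input_max = 1, act_max = rep(1, length(weights)),
              weight_max = rep(0, length(weights)))
  ann_to_sleep_ann(net, ref, sleep_config(thresholds = thresholds,
                                          scale_multiplier = 1))
}

# Small random wake net with reproducible weights.
random_net <- function(layer_sizes, seed = 1, init_range = 0.5) {
  init_network(layer_sizes, training_config(init_range = init_range,
                                            seed = seed))
}

# Two-task synthetic image stream at desk scale.
fixture_stream <- function(seed, n_train = 100L, n_test = 50L) {
  fx <- synthetic_fixture(n_train = n_train, n_test = n_test, seed = seed,
                          n_classes = 4L, n_on_pixels = 20L, overlap = 14L,
                          noise = 0.05)
  build_task_stream(fx$train, fx$test, "incremental", classes_per_task = 2L)
}

# Sleep hyperparameter candidate grids used when tuning on the synthetic
# fixture (searched against training-set accuracy, as the method prescribes).
fixture_tune_grid <- function() {
  list(thresholds = c(1, 2), scale_multipliers = c(2, 4),
       inc = c(5e-5, 2e-4), dec = c(5e-5, 2e-4))
}

# Candidate grids for the toy binary-patch task.
toy_tune_grid <- function() {
  list(thresholds = c(0.2, 0.5, 1), scale_multipliers = c(2, 4),
       inc = c(0.002, 0.01), dec = c(0.02, 0.05))
}

# Co-spike (C) and post-only (D) counts per weight layer from a spike log.
spike_log_counts <- function(spike_log) {
  L <- length(spike_log) - 1L
  lapply(seq_len(L), function(l) {
    pre <- spike_log[[l]]
    post <- spike_log[[l + 1L]]
    list(C = t(post) %*% pre, D = t(post) %*% (1 - pre))
  })
}
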