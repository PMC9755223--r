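#' Sleep-phase hyperparameters
#'
#' Controls the offline consolidation phase: its duration in time steps, the
#' Hebbian potentiation/depression magnitudes, per-layer spike thresholds,
#' and multiplicative adjustments on top of the normalisation-derived
#' propagation scales. Thresholds and multipliers recycle over weight
#' layers, so a scalar applies network-wide. These knobs are task-dependent;
#' [tune_sleep()] searches them against training-set accuracy.
#'
#' @param duration Number of sleep time steps (`Ts`).
#' @param inc Weight increment when pre- and post-synaptic units co-spike.
#' @param dec Weight decrement when the post-synaptic unit spikes without
#'   the pre-synaptic one.
#' @param thresholds Per-weight-layer spike thresholds (recycled).
#' @param scale_multiplier Per-weight-layer factors applied on top of the
#'   normalisation-derived scales (recycled).
#' @param input_mode `"bernoulli_mean"` draws each input pixel on with
#'   probability equal to its stored mean intensity; `"bernoulli_uniform"`
#'   uses a flat rate `uniform_p` (the fully random stimulation used for
#'   replay analysis).
#' @param uniform_p Flat on-probability for `"bernoulli_uniform"`.
#' @param keep_spike_log Record per-step, per-layer spike vectors (needed by
#'   the replay diagnostics; off by default to bound memory).
#' @param use_max_weight Include the max-weight guard in the normalisation.
#' @param seed Optional integer seed for the sleep noise.
#' @return An object of class `sleep_config`.
#' @export
sleep_config <- function(duration = 10000L, inc = 0.001, dec = 0.0001,
                         thresholds = 1, scale_multiplier = 1,
                         input_mode = c("bernoulli_mean", "bernoulli_uniform"),
                         uniform_p = 0.5, keep_spike_log = FALSE,
                         use_max_weight = TRUE, seed = NULL) {
  stopifnot(duration >= 0, inc >= 0, dec >= 0, all(thresholds > 0),
            all(scale_multiplier >= 0), uniform_p >= 0, uniform_p <= 1)
  structure(list(duration = as.integer(duration), inc = inc, dec = dec,
                 thresholds = thresholds, scale_multiplier = scale_multiplier,
                 input_mode = match.arg(input_mode), uniform_p = uniform_p,
                 keep_spike_log = keep_spike_log,
                 use_max_weight = use_max_weight, seed = seed),
            class = "sleep_config")
}

#' Reference activation maxima for sleep conversion
#'
#' One wake pass over reference data (the most recent task's training set)
#' recording, per weight layer, the maximum observed activation and the
#' maximum weight, plus the maximum input value. These feed the data-based
#' layer normalisation of [ann_to_sleep_ann()].
#'
#' @param net A `dense_net` in wake mode.
#' @param x Reference inputs, one sample per row.
#' @return List with `input_max`, `act_max` (per weight layer) and
#'   `weight_max` (per weight layer).
#' @export
reference_activations <- function(net, x) {
  fwd <- forward_wake(net, x)
  L <- n_weight_layers(net)
  act_max <- vapply(seq_len(L), function(l)
    max(fwd$activations[[l + 1L]], 0), numeric(1))
  weight_max <- vapply(net$weights, max, numeric(1))
  list(input_max = max(as.matrix(x)), act_max = act_max,
       weight_max = weight_max)
}

# Data-based layer normalisation: each layer l gets a propagation-time scale
# lambda_{l-1} / lambda_l, where lambda_l is the larger of the maximum
# activation observed in layer l and (optionally) the maximum weight into it,
# and lambda_0 is the maximum input value. Propagating the reference data
# with these scales bounds every layer's scaled activation by 1. Weights are
# never rewritten; the scale is applied at propagation time.
compute_sleep_scales <- function(ref, use_max_weight = TRUE) {
  L <- length(ref$act_max)
  scales <- numeric(L)
  prev <- ref$input_max
  if (!is.finite(prev) || prev <= 0) prev <- 1
  for (l in seq_len(L)) {
    lambda <- if (use_max_weight) max(ref$act_max[l], ref$weight_max[l])
              else ref$act_max[l]
    if (!is.finite(lambda) || lambda <= 0) {
      warning("layer ", l, " has no positive reference activation; ",
              "scale defaults to 1")
      lambda <- prev
    }
    scales[l] <- prev / lambda
    prev <- lambda
  }
  scales
}

#' Convert a trained network to sleep (spiking) semantics
#'
#' Switches the activation to a Heaviside spike rule viewed through
#' per-layer scale factors and thresholds. The stored weight matrices are
#' shared, unscaled and untouched: scaling happens at propagation time only.
#' Scales come from the data-based normalisation of the reference
#' activations, multiplied by `config$scale_multiplier`; thresholds come
#' from the config. Membrane voltages start at zero.
#'
#' @param net A trained `dense_net` in wake mode.
#' @param ref Output of [reference_activations()] on the last training data.
#' @param config A [sleep_config()].
#' @return An object of class `sleep_net`: list with `weights`,
#'   `layer_sizes`, `scales`, `thresholds`, voltage list `v` (one vector per
#'   non-input layer) and `mode = "sleep"`.
#' @export
ann_to_sleep_ann <- function(net, ref, config = sleep_config()) {
  L <- n_weight_layers(net)
  scales <- compute_sleep_scales(ref, config$use_max_weight) *
    rep_len(config$scale_multiplier, L)
  thresholds <- rep_len(config$thresholds, L)
  v <- lapply(seq_len(L), function(l) numeric(net$layer_sizes[l + 1L]))
  structure(list(weights = net$weights, layer_sizes = net$layer_sizes,
                 scales = scales, thresholds = thresholds, v = v,
                 mode = "sleep"),
            class = "sleep_net")
}

#' Convert a sleep network back to wake semantics
#'
#' The weights were stored unscaled throughout the sleep phase, so the
#' conversion simply carries them over and discards voltages and spike
#' state; no residual scaling factor remains in the wake-mode forward pass.
#'
#' @param snet A `sleep_net`.
#' @return A `dense_net` in wake mode holding the (possibly updated) weights.
#' @export
sleep_ann_to_ann <- function(snet) {
  structure(list(layer_sizes = snet$layer_sizes, weights = snet$weights,
                 mode = "wake"),
            class = "dense_net")
}

#' Draw one noisy binary input vector for the sleep phase
#'
#' Each input element is independently set to 1 with probability equal to
#' its stored mean intensity (rates are at most one per step, so the
#' per-step Poisson event reduces to a Bernoulli draw). A fresh vector is
#' drawn at every sleep time step.
#'
#' @param stats An `input_stats` object (mean intensities in `[0, 1]`).
#' @return Binary numeric vector of input spikes.
#' @export
poisson_input <- function(stats) {
  p <- stats$mean_intensity
  if (any(p < 0) || any(p > 1)) {
    warning("mean intensities outside [0, 1] clipped")
    p <- pmin(pmax(p, 0), 1)
  }
  as.numeric(stats::runif(length(p)) < p)
}

#' One integrate-and-fire forward pass through the sleep network
#'
#' For each layer in order, adds the scaled synaptic drive of the previous
#' layer's spikes to the membrane voltages, emits a spike wherever the
#' voltage strictly exceeds the layer threshold, and resets spiking
#' voltages to zero. Non-spiking voltages persist to the next time step; no
#' leak and no refractory period beyond the reset.
#'
#' @param snet A `sleep_net`.
#' @param s1 Binary input spike vector.
#' @param n_layers Optional cap on how many weight layers to propagate
#'   through (used by the replay analysis to exclude the output layer).
#' @return List with the updated `snet` and `spikes`, the per-layer spike
#'   vectors (input first).
#' @export
sleep_forward_pass <- function(snet, s1, n_layers = NULL) {
  L <- if (is.null(n_layers)) length(snet$weights) else n_layers
  spikes <- vector("list", L + 1L)
  spikes[[1L]] <- as.numeric(s1)
  for (l in seq_len(L)) {
    drive <- snet$scales[l] * as.numeric(snet$weights[[l]] %*% spikes[[l]])
    v <- snet$v[[l]] + drive
    s <- as.numeric(v > snet$thresholds[l])
    v[s == 1] <- 0
    snet$v[[l]] <- v
    spikes[[l + 1L]] <- s
  }
  list(snet = snet, spikes = spikes)
}

#' Hebbian weight update from one step's spikes
#'
#' For every synapse whose post-synaptic unit spiked this step: add `inc` if
#' the pre-synaptic unit also spiked, subtract `dec` if it stayed silent.
#' Synapses onto silent post-synaptic units are untouched. The update is
#' applied to the unscaled stored weights; the output layer participates
#' like any other.
#'
#' @param snet A `sleep_net`.
#' @param spikes Per-layer spike vectors from [sleep_forward_pass()].
#' @param inc,dec Potentiation / depression magnitudes.
#' @return The `sleep_net` with updated weights.
#' @export
sleep_backward_pass <- function(snet, spikes, inc, dec) {
  for (l in seq_along(snet$weights)) {
    post <- spikes[[l + 1L]]
    if (!any(post == 1)) next
    pre <- spikes[[l]]
    delta <- ifelse(pre == 1, inc, -dec)
    rows <- which(post == 1)
    snet$weights[[l]][rows, ] <- snet$weights[[l]][rows, , drop = FALSE] +
      matrix(delta, nrow = length(rows), ncol = length(pre), byrow = TRUE)
  }
  snet
}

#' Run a full sleep replay consolidation episode
#'
#' Converts the trained network to sleep semantics, then for `duration`
#' time steps draws a fresh noisy binary input, propagates it by
#' integrate-and-fire dynamics, and applies the local Hebbian rule; finally
#' converts back to wake mode. The noise rates are the stored mean input
#' intensities (or a flat rate, see [sleep_config()]); no stored examples
#' are ever replayed explicitly.
#'
#' @param net A trained `dense_net` in wake mode.
#' @param stats An `input_stats` populated with all past training inputs.
#' @param config A [sleep_config()].
#' @param reference_data Inputs of the most recent training set, used to
#'   recompute the layer normalisation. If `NULL`, unit base scales are used
#'   (the multiplier still applies).
#' @return An object of class `sleep_result`: list with `net` (wake mode,
#'   updated weights), `scales`, `thresholds` and, if requested,
#'   `spike_log` (per layer, a `duration` x neurons binary matrix, the
#'   input layer included).
#' @export
sleep_replay <- function(net, stats, config = sleep_config(),
                         reference_data = NULL) {
  if (!inherits(stats, "input_stats") || stats$n_samples_seen == 0L)
    stop("sleep requires populated input statistics")
  if (length(stats$mean_intensity) != net$layer_sizes[1L])
    stop("input statistics dimension does not match the network input size")
  if (!is.null(config$seed)) {
    # a seeded sleep episode draws its noise from its own stream and leaves
    # the ambient RNG state untouched, so interleaving (or disabling) sleep
    # does not perturb the surrounding training trajectory
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(config$seed)
  }
  ref <- if (is.null(reference_data))
    list(input_max = 1, act_max = rep(1, n_weight_layers(net)),
         weight_max = rep(0, n_weight_layers(net)))
  else reference_activations(net, reference_data)
  snet <- ann_to_sleep_ann(net, ref, config)
  draw_stats <- stats
  if (config$input_mode == "bernoulli_uniform")
    draw_stats$mean_intensity <- rep(config$uniform_p,
                                     length(stats$mean_intensity))
  log <- NULL
  if (config$keep_spike_log && config$duration > 0L)
    log <- lapply(c(net$layer_sizes[1L],
                    net$layer_sizes[-1L]), function(k)
      matrix(0L, nrow = config$duration, ncol = k))
  for (t in seq_len(config$duration)) {
    s1 <- poisson_input(draw_stats)
    fp <- sleep_forward_pass(snet, s1)
    snet <- fp$snet
    snet <- sleep_backward_pass(snet, fp$spikes, config$inc, config$dec)
    if (!is.null(log))
      for (l in seq_along(log)) log[[l]][t, ] <- fp$spikes[[l]]
  }
  structure(list(net = sleep_ann_to_ann(snet), scales = snet$scales,
                 thresholds = snet$thresholds, spike_log = log),
            class = "sleep_result")
}
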