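test_that("conversion derives data-based scales without touching weights", {
  net <- random_net(c(5, 4, 3), seed = 10, init_range = 0.3)
  # make activity strictly positive so every layer has a reference maximum
  net$weights <- lapply(net$weights, abs)
  x <- matrix(runif(20 * 5), ncol = 5)
  ref <- reference_activations(net, x)
  w_before <- net$weights
  snet <- ann_to_sleep_ann(net, ref, sleep_config())
  expect_identical(net$weights, w_before)
  expect_identical(snet$weights, w_before)
  expect_true(all(vapply(snet$v, function(v) all(v == 0), logical(1))))

  # brute-force check: propagating the reference batch with the scales
  # bounds every layer's scaled activation by the maximum input value
  scales <- snet$scales
  a <- x
  for (l in seq_along(scales)) {
    a <- pmax(scales[l] * (a %*% t(net$weights[[l]])), 0)
    expect_lte(max(a), ref$input_max + 1e-9)
  }

  # without the max-weight guard the bound is attained exactly per layer
  scales2 <- sleepreplay:::compute_sleep_scales(ref, use_max_weight = FALSE)
  a <- x
  for (l in seq_along(scales2)) {
    a <- pmax(scales2[l] * (a %*% t(net$weights[[l]])), 0)
    expect_equal(max(a), ref$input_max, tolerance = 1e-9)
  }

  # a silent layer falls back to scale 1 with a warning
  ref_dead <- list(input_max = 1, act_max = c(0, 1.5), weight_max = c(0, 0))
  expect_warning(
    s_dead <- sleepreplay:::compute_sleep_scales(ref_dead,
                                                 use_max_weight = FALSE),
    "scale defaults to 1")
  expect_equal(s_dead[1], 1)
})

test_that("integrate-and-fire forward pass matches hand-computed traces", {
  snet <- manual_sleep_net(list(rbind(c(1, -1), c(0.5, 0.5))),
                           thresholds = 0.6)
  fp <- sleep_forward_pass(snet, c(1, 0))
  expect_equal(fp$spikes[[2]], c(1, 0))
  expect_equal(fp$snet$v[[1]], c(0, 0.5))

  # second identical step: the silent neuron's voltage carries over
  fp2 <- sleep_forward_pass(fp$snet, c(1, 0))
  expect_equal(fp2$spikes[[2]], c(1, 1))
  expect_equal(fp2$snet$v[[1]], c(0, 0))

  # subthreshold drive accumulates across steps and fires on step two
  sub <- manual_sleep_net(list(matrix(0.4)), thresholds = 0.6)
  s1 <- sleep_forward_pass(sub, 1)
  expect_equal(s1$spikes[[2]], 0)
  expect_equal(s1$snet$v[[1]], 0.4)
  s2 <- sleep_forward_pass(s1$snet, 1)
  expect_equal(s2$spikes[[2]], 1)
  expect_equal(s2$snet$v[[1]], 0)

  # the comparison is strict: voltage exactly at threshold does not fire
  exact <- manual_sleep_net(list(matrix(0.6)), thresholds = 0.6)
  expect_equal(sleep_forward_pass(exact, 1)$spikes[[2]], 0)

  # zero weights propagate nothing
  silent <- manual_sleep_net(list(matrix(0, 3, 3), matrix(0, 2, 3)),
                             thresholds = 0.5)
  fp3 <- sleep_forward_pass(silent, c(1, 1, 1))
  expect_equal(fp3$spikes[[2]], rep(0, 3))
  expect_equal(fp3$spikes[[3]], rep(0, 2))
})

test_that("Hebbian backward pass applies the local rule synapse-by-synapse", {
  snet <- manual_sleep_net(list(matrix(0, 2, 2)), thresholds = 1)
  out <- sleep_backward_pass(snet, list(c(1, 0), c(1, 0)),
                             inc = 0.01, dec = 0.001)
  expect_equal(out$weights[[1]], rbind(c(0.01, -0.001), c(0, 0)))

  # no post-synaptic spikes anywhere: nothing changes
  out2 <- sleep_backward_pass(snet, list(c(1, 1), c(0, 0)),
                              inc = 0.01, dec = 0.001)
  expect_identical(out2$weights, snet$weights)
})

test_that("total sleep weight change decomposes into spike-count terms", {
  # dyadic increments and grid-aligned weights make the identity exact
  inc <- 2^-7
  dec <- 2^-9
  for (seed in 1:3) {
    net <- random_net(c(12, 20, 15, 6), seed = seed, init_range = 0.5)
    net$weights <- lapply(net$weights, function(w) round(w * 2^9) / 2^9)
    stats <- update_input_statistics(
      new_input_statistics(12),
      matrix(runif(12 * 5, 0.2, 0.9), ncol = 12))
    cfg <- sleep_config(duration = 50, inc = inc, dec = dec, thresholds = 0.5,
                        scale_multiplier = 1, keep_spike_log = TRUE,
                        seed = seed + 100)
    res <- sleep_replay(net, stats, cfg)
    counts <- spike_log_counts(res$spike_log)
    for (l in seq_along(net$weights)) {
      delta <- res$net$weights[[l]] - net$weights[[l]]
      expect_identical(delta, inc * counts[[l]]$C - dec * counts[[l]]$D)
      # conservation of silence: untouched rows for never-spiking posts
      silent <- which(colSums(res$spike_log[[l + 1L]]) == 0)
      expect_identical(res$net$weights[[l]][silent, , drop = FALSE],
                       net$weights[[l]][silent, , drop = FALSE])
    }
  }
})

test_that("plasticity direction is monotone in inc and dec", {
  net <- random_net(c(10, 8, 4), seed = 4, init_range = 0.5)
  stats <- update_input_statistics(new_input_statistics(10),
                                   matrix(runif(50, 0.3, 0.9), ncol = 10))
  up <- sleep_replay(net, stats,
                     sleep_config(duration = 40, inc = 0.01, dec = 0,
                                  thresholds = 0.5, seed = 1))
  for (l in seq_along(net$weights))
    expect_true(all(up$net$weights[[l]] >= net$weights[[l]]))
  down <- sleep_replay(net, stats,
                       sleep_config(duration = 40, inc = 0, dec = 0.01,
                                    thresholds = 0.5, seed = 1))
  for (l in seq_along(net$weights))
    expect_true(all(down$net$weights[[l]] <= net$weights[[l]]))
})

test_that("noisy input generator follows the stored mean intensities", {
  d <- 50
  zeros <- new_input_statistics(d)
  expect_equal(poisson_input(zeros), rep(0, d))
  ones <- zeros; ones$mean_intensity <- rep(1, d)
  expect_equal(poisson_input(ones), rep(1, d))

  half <- zeros; half$mean_intensity <- rep(0.5, d)
  set.seed(123)
  draws <- replicate(200, poisson_input(half))
  expect_equal(mean(draws), 0.5, tolerance = 0.02)

  dirty <- zeros; dirty$mean_intensity <- c(rep(0.5, d - 2), -0.3, 1.7)
  expect_warning(s <- poisson_input(dirty), "clipped")
  expect_equal(s[d - 1], 0)
  expect_equal(s[d], 1)
})

test_that("a zero scale multiplier silences the whole network", {
  net <- random_net(c(10, 8, 4), seed = 2, init_range = 0.5)
  stats <- update_input_statistics(new_input_statistics(10),
                                   matrix(runif(50, 0.5, 1), ncol = 10))
  res <- sleep_replay(net, stats,
                      sleep_config(duration = 30, scale_multiplier = 0,
                                   thresholds = 0.5, keep_spike_log = TRUE,
                                   seed = 3))
  expect_equal(sum(res$spike_log[[2]]), 0)
  expect_equal(sum(res$spike_log[[3]]), 0)
  expect_identical(res$net$weights, net$weights)
})

test_that("sleep refuses to run without populated input statistics", {
  net <- random_net(c(5, 3), seed = 1)
  expect_error(sleep_replay(net, new_input_statistics(5)),
               "populated input statistics")
  stats_bad <- update_input_statistics(new_input_statistics(4),
                                       matrix(0.5, 2, 4))
  expect_error(sleep_replay(net, stats_bad), "dimension")
})

test_that("wake-sleep-wake conversion is stable and scale-free", {
  net <- random_net(c(6, 5, 3), seed = 8, init_range = 0.3)
  x <- matrix(runif(30), ncol = 6)
  ref <- reference_activations(net, x)
  snet <- ann_to_sleep_ann(net, ref, sleep_config())
  back <- sleep_ann_to_ann(snet)
  expect_identical(back$weights, net$weights)
  expect_equal(back$mode, "wake")
  # wake logits equal the explicit matrix product, no residual scaling
  f <- forward_wake(back, x)
  manual <- pmax(x %*% t(net$weights[[1]]), 0) %*% t(net$weights[[2]])
  expect_equal(f$activations[[3]], manual, tolerance = 1e-12)
  # a second conversion from the same reference succeeds unchanged
  snet2 <- ann_to_sleep_ann(back, ref, sleep_config())
  expect_identical(snet2$scales, snet$scales)
})

test_that("toy patch sleep suppresses old-task-unique input to new outputs", {
  cfg <- sleep_config(duration = 2000, inc = 0.002, dec = 0.02,
                      thresholds = 0.5, scale_multiplier = 2)
  res <- run_patches_experiment(overlap = 14, seed = 1, sleep_cfg = cfg)
  pre <- res$nets[["T2"]]; post <- res$nets[["SRC"]]
  p <- res$patches
  t1u <- which(p$categories == "unique_t1")
  t2_outs <- p$tasks[[2]] + 1L
  mean_pre <- mean(pre$weights[[1]][t2_outs, t1u])
  mean_post <- mean(post$weights[[1]][t2_outs, t1u])
  expect_lt(mean_post, mean_pre)
  # input drive from the first old-task image to the new task's outputs drops
  dc <- drive_change(pre, post, p$x[1, , drop = FALSE], layer = 1,
                     neuron_set = t2_outs)
  expect_true(all(dc$delta < 0))
})
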