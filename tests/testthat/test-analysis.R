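# A net whose first hidden layer reproduces its (non-negative) input:
# activations are then fully controlled by the test.
passthrough_net <- function(d, n_out = 2) {
  structure(list(layer_sizes = c(d, d, n_out),
                 weights = list(diag(d), matrix(0.1, n_out, d)),
                 mode = "wake"),
            class = "dense_net")
}

test_that("class correlation matrix matches a brute-force pairwise oracle", {
  acts <- rbind(c(1, 0, 2, 0.5),   # class 0
                c(0.8, 0.1, 1.9, 0.4),
                c(0, 2, 0.3, 1),   # class 1
                c(0.1, 1.7, 0.2, 1.2))
  y <- c(0L, 0L, 1L, 1L)
  net <- passthrough_net(4)
  m <- class_correlation_matrix(net, acts, y, layer = 1)

  oracle <- function(i, j) cor(acts[i, ], acts[j, ])
  expect_equal(m["0", "0"], oracle(1, 2), tolerance = 1e-12)
  expect_equal(m["1", "1"], oracle(3, 4), tolerance = 1e-12)
  expect_equal(m["0", "1"],
               mean(c(oracle(1, 3), oracle(1, 4),
                      oracle(2, 3), oracle(2, 4))), tolerance = 1e-12)
  expect_equal(m, t(m), tolerance = 1e-12)
})

test_that("degenerate activation patterns are reported as missing", {
  net <- passthrough_net(3)
  # constant activation vectors: zero variance, correlation undefined
  x <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5), c(0.2, 0.9, 0.1))
  m <- class_correlation_matrix(net, x, c(0L, 0L, 1L), layer = 1)
  expect_true(is.na(m["0", "0"]))
  expect_true(is.na(m["0", "1"]))
  # a single-sample class has no within-class pair
  expect_true(is.na(m["1", "1"]))
})

test_that("task-neuron ranking matches an independent sort oracle", {
  # block structure: neurons 1..100 fire only for the first class
  counts <- matrix(0, nrow = 150, ncol = 2, dimnames = list(NULL, 0:1))
  counts[1:100, 1] <- 5
  counts[101:150, 2] <- 3
  r <- suppressWarnings(rank_task_neurons(counts, k = 100))
  expect_identical(r$sets[[1]], 1:100)
  expect_identical(r$sets[[2]], 101:150)

  # ties break to the lower neuron index and lower class column
  tied <- matrix(c(2, 2, 2, 2), nrow = 2, dimnames = list(NULL, 0:1))
  rt <- suppressWarnings(rank_task_neurons(tied, k = 1))
  expect_identical(rt$assignment, c(1L, 1L))
  expect_identical(rt$sets[[1]], 1L)

  # random tables: agreement with a brute-force oracle, sets disjoint
  set.seed(31)
  for (rep in 1:5) {
    cnt <- matrix(rpois(60 * 3, 4), nrow = 60, ncol = 3,
                  dimnames = list(NULL, 0:2))
    r2 <- suppressWarnings(rank_task_neurons(cnt, k = 10))
    assign_oracle <- apply(cnt, 1, which.max)
    expect_identical(r2$assignment, as.integer(assign_oracle))
    for (ci in 1:3) {
      pool <- which(assign_oracle == ci)
      ord <- pool[order(-cnt[pool, ci], pool)]
      expect_identical(r2$sets[[ci]], ord[seq_len(min(10, length(ord)))])
    }
    expect_length(Reduce(intersect, r2$sets), 0L)
  }
})

test_that("firing-rate comparison reproduces the closed-form t statistic", {
  # craft a spike log with exact rates: 10 steps, 8 neurons
  log1 <- matrix(0L, nrow = 10, ncol = 8)
  rates <- c(2, 3, 4, 1, 1, 2, 0, 1)   # spikes per neuron
  for (j in 1:8) if (rates[j] > 0) log1[seq_len(rates[j]), j] <- 1L
  spike_log <- list(matrix(0L, 10, 1), log1)
  sets <- list(taskA = list(1:4))
  res <- sleep_firing_comparison(spike_log, sets, layer = 1, n_random = 4,
                                 random_set = 5:8, n_comparisons = 1,
                                 alternative = "greater", var_equal = TRUE)

  a <- rates[1:4] / 10; b <- rates[5:8] / 10
  sp <- sqrt(((3 * var(a)) + (3 * var(b))) / 6)
  t_oracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 6)
  expect_equal(res$p_value, pt(t_oracle, 6, lower.tail = FALSE),
               tolerance = 1e-12)

  # all rates equal: degenerate comparison collapses to t = 0
  flat <- list(matrix(0L, 10, 1),
               matrix(rep(c(1L, 0L), c(2, 8)), nrow = 10, ncol = 8))
  res0 <- sleep_firing_comparison(flat, sets, layer = 1, n_random = 4,
                                  random_set = 5:8, n_comparisons = 1)
  expect_equal(res0$t, 0)

  expect_error(sleep_firing_comparison(NULL, sets), "empty spike log")
})

test_that("firing-rate test holds its nominal size under the null", {
  set.seed(77)
  alpha <- 0.05
  n_sim <- 1000
  rejections <- 0
  for (i in seq_len(n_sim)) {
    log1 <- matrix(rbinom(20 * 60, 1, 0.2), nrow = 20, ncol = 60)
    sets <- list(t1 = list(sample(60, 20)))
    res <- sleep_firing_comparison(list(matrix(0L, 20, 1), log1), sets,
                                   layer = 1, random_set = sample(60, 20),
                                   n_comparisons = 1)
    if (res$p_value <= alpha) rejections <- rejections + 1
  }
  expect_lte(rejections / n_sim, alpha + 2 * sqrt(alpha * (1 - alpha) / n_sim))
})

test_that("drive change is zero for identical nets and linear in weights", {
  net <- random_net(c(4, 3, 2), seed = 5, init_range = 0.2)
  x <- matrix(runif(20), ncol = 4)
  same <- drive_change(net, net, x, layer = 1, neuron_set = 1:3)
  expect_equal(same$delta, rep(0, 3))

  bumped <- net
  delta_w <- 0.37
  bumped$weights[[1]][2, 3] <- bumped$weights[[1]][2, 3] + delta_w
  dc <- drive_change(net, bumped, x, layer = 1, neuron_set = 2)
  expect_equal(dc$delta, delta_w * mean(x[, 3]), tolerance = 1e-12)

  other <- random_net(c(4, 5, 2), seed = 6)
  expect_error(drive_change(net, other, x, 1, 1), "mismatched")
})

test_that("toy weight histograms partition weights exactly by category", {
  p <- generate_patches(overlap = 14, seed = 2)
  cfg <- training_config(momentum = 0, dropout_rate = 0, seed = 2)
  net <- init_network(c(100, 4), cfg)
  net <- train_to_convergence(net, p$x[1:2, ], p$y[1:2])
  h <- weight_category_histograms(net, p)

  n_rows <- table(h$pixel_category, h$to_task)
  expect_true(all(n_rows["overlap", ] == 28 * 2))       # 2x14 px, 2 outputs
  expect_true(all(n_rows["unique_t1", ] == 12 * 2))
  expect_true(all(n_rows["unique_t2", ] == 12 * 2))

  # after first-task training only, weights from old-task pixels to the
  # old-task outputs carry positive mean
  expect_gt(mean(h$weight[h$pixel_category == "unique_t1" & h$to_task == 1]),
            0)

  p0 <- generate_patches(overlap = 0, seed = 2)
  net0 <- init_network(c(100, 4), cfg)
  h0 <- weight_category_histograms(net0, p0)
  expect_false("overlap" %in% h0$pixel_category)

  small <- init_network(c(25, 4), cfg)
  expect_error(weight_category_histograms(small, p), "does not match")
})

test_that("weight cosine similarity behaves as a proper cosine", {
  w <- list(rbind(c(1, 2), c(3, -1)))
  expect_equal(weight_cosine_similarity(w, w), 1)
  expect_equal(weight_cosine_similarity(w, lapply(w, `-`)), -1)

  a <- list(rbind(c(1, 0), c(0, 1)))
  b <- list(rbind(c(1, 1), c(0, 0)))
  # by hand: dot = 1, |a| = sqrt(2), |b| = sqrt(2)
  expect_equal(weight_cosine_similarity(a, b), 0.5, tolerance = 1e-12)

  expect_warning(z <- weight_cosine_similarity(
    list(matrix(0, 2, 2)), a), "zero weight")
  expect_true(is.na(z))
  expect_error(weight_cosine_similarity(a, list(matrix(1, 3, 2))),
               "mismatched")
})

test_that("sequentially trained toy weights keep a positive trace of task 1", {
  seq_run <- run_patches_experiment(overlap = 14, seed = 3)
  p <- seq_run$patches
  cfg <- training_config(momentum = 0, dropout_rate = 0, seed = 3)
  t1_only <- init_network(c(100, 4), cfg)
  t1_only <- train_to_convergence(t1_only, p$x[1:2, ], p$y[1:2])
  expect_gt(weight_cosine_similarity(seq_run$net, t1_only), 0)
})

test_that("sparseness measures stay within their ranges", {
  net <- random_net(c(6, 10, 3), seed = 9, init_range = 0.3)
  x <- matrix(runif(30), ncol = 6)
  sp <- activation_sparseness(net, x, layer = 1)
  expect_gte(sp$inactive_fraction, 0)
  expect_lte(sp$inactive_fraction, 1)
  expect_gte(sp$treves_rolls, 0)
  expect_lte(sp$treves_rolls, 1 + 1e-12)
})
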