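#' Class-by-class correlation matrix of hidden-layer activations
#'
#' Entry `(a, b)` is the mean Pearson correlation of the hidden activation
#' vectors over all cross pairs of samples from classes `a` and `b`
#' (distinct-sample pairs only on the diagonal). Decorrelation of
#' between-class entries after a sleep phase indicates that the network has
#' allocated distinct populations to distinct classes.
#'
#' @param net A `dense_net` in wake mode.
#' @param x,y Evaluation data (labels 0-based).
#' @param layer Hidden layer index (1 = first hidden layer).
#' @return A symmetric numeric matrix with class labels as dimnames.
#'   Pairs involving a zero-variance activation vector, and diagonal cells
#'   with fewer than two samples, are reported as `NA`.
#' @export
class_correlation_matrix <- function(net, x, y, layer = 1L) {
  d <- check_data(net, x, y)
  x <- d$x; y <- d$y
  fwd <- forward_wake(net, x)
  acts <- fwd$activations[[layer + 1L]]
  sds <- apply(acts, 1L, stats::sd)
  cc <- suppressWarnings(stats::cor(t(acts)))
  cc[sds == 0 | is.na(sds), ] <- NA
  cc[, sds == 0 | is.na(sds)] <- NA
  classes <- sort(unique(y))
  k <- length(classes)
  out <- matrix(NA_real_, k, k, dimnames = list(classes, classes))
  for (i in seq_len(k)) for (j in i:k) {
    si <- which(y == classes[i]); sj <- which(y == classes[j])
    block <- cc[si, sj, drop = FALSE]
    if (i == j) {
      if (length(si) < 2L) next
      vals <- block[lower.tri(block)]
    } else {
      vals <- as.vector(block)
    }
    out[i, j] <- out[j, i] <- mean(vals, na.rm = FALSE)
  }
  out
}

#' Mean between-class correlation
#'
#' Convenience summary of [class_correlation_matrix()]: the mean of the
#' off-diagonal entries.
#'
#' @param mat A class correlation matrix.
#' @return Scalar mean off-diagonal correlation.
#' @export
mean_between_class_correlation <- function(mat)
  mean(mat[row(mat) != col(mat)], na.rm = TRUE)

#' Identify task-specific hidden neurons of a sleep-mode network
#'
#' Presents examples of each class to the converted network for a number of
#' forward passes (input pixels encoded as Bernoulli spikes with
#' probability equal to the example's intensities, cycling through the
#' class's examples; membrane voltages persist within a class presentation
#' and reset between classes) and counts spikes per hidden neuron. The
#' output layer is excluded from propagation so that classification
#' readout does not bias the assignment. Each neuron is assigned to the
#' class that maximally activates it (ties to the lower class index); per
#' class the `k` highest-count assigned neurons are returned (count ties to
#' the lower neuron index).
#'
#' @param snet A `sleep_net` (see [ann_to_sleep_ann()]).
#' @param x,y Labelled wake-format examples used as stimulation sources.
#' @param k Neurons to return per class.
#' @param passes Forward passes per class.
#' @return List with `sets` (per class, list of neuron index vectors per
#'   hidden layer), `counts` (per hidden layer, neuron x class spike-count
#'   matrix) and `assignment` (per hidden layer, the winning class per
#'   neuron).
#' @export
identify_task_neurons <- function(snet, x, y, k = 100L, passes = 25L) {
  x <- as.matrix(x); y <- as.integer(y)
  L_hidden <- length(snet$weights) - 1L
  if (L_hidden < 1L) stop("network has no hidden layers")
  classes <- sort(unique(y))
  counts <- lapply(seq_len(L_hidden), function(l)
    matrix(0, nrow = snet$layer_sizes[l + 1L], ncol = length(classes),
           dimnames = list(NULL, classes)))
  for (ci in seq_along(classes)) {
    pool <- which(y == classes[ci])
    work <- snet
    for (l in seq_along(work$v)) work$v[[l]] <- numeric(length(work$v[[l]]))
    for (p in seq_len(passes)) {
      ex <- x[pool[(p - 1L) %% length(pool) + 1L], ]
      s1 <- as.numeric(stats::runif(length(ex)) < ex)
      fp <- sleep_forward_pass(work, s1, n_layers = L_hidden)
      work <- fp$snet
      for (l in seq_len(L_hidden))
        counts[[l]][, ci] <- counts[[l]][, ci] + fp$spikes[[l + 1L]]
    }
  }
  ranked <- lapply(counts, rank_task_neurons, k = k)
  sets <- lapply(seq_along(classes), function(ci)
    lapply(ranked, function(r) r$sets[[ci]]))
  names(sets) <- classes
  list(sets = sets, counts = counts,
       assignment = lapply(ranked, function(r) classes[r$assignment]))
}

#' Rank neurons into per-class top-k sets from a spike-count table
#'
#' Assigns every neuron to the class with its maximal spike count (ties to
#' the lower class index) and returns, per class, the `k` assigned neurons
#' with the highest counts (count ties to the lower neuron index). The
#' resulting sets are disjoint across classes by construction.
#'
#' @param counts Neuron x class spike-count matrix.
#' @param k Neurons to return per class.
#' @return List with `sets` (per class, integer neuron indices) and
#'   `assignment` (winning class column per neuron).
#' @export
rank_task_neurons <- function(counts, k = 100L) {
  assignment <- max.col(counts, "first")
  sets <- lapply(seq_len(ncol(counts)), function(ci) {
    pool <- which(assignment == ci)
    if (length(pool) == 0L) return(integer(0))
    if (length(pool) < k)
      warning("class column ", ci, " has only ", length(pool),
              " assigned neurons (k = ", k, ")")
    pool[order(-counts[pool, ci], pool)][seq_len(min(k, length(pool)))]
  })
  names(sets) <- colnames(counts)
  list(sets = sets, assignment = assignment)
}

#' Compare sleep firing rates of task-specific vs. random neurons
#'
#' From a sleep spike log (typically recorded under uniform-random input to
#' avoid bias from the task-averaged statistics), computes each neuron's
#' mean firing rate and tests whether the task-specific neurons fired at a
#' higher rate than a random subset of the same layer. Per-class sets
#' belonging to one task are concatenated before testing; p-values carry a
#' Bonferroni correction for the number of comparisons made.
#'
#' @param spike_log Per-layer spike matrices from [sleep_replay()] (input
#'   layer first).
#' @param task_sets Named list: for each task, the concatenated hidden
#'   neuron indices of its classes, per hidden layer (as produced from
#'   [identify_task_neurons()] sets).
#' @param layer Hidden layer to analyse (1 = first hidden).
#' @param n_random Size of the random comparison subset.
#' @param alternative `"greater"` (one-sided, the headline test) or
#'   `"two.sided"`.
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @param n_comparisons Bonferroni factor (defaults to the number of tasks).
#' @param random_set Optional explicit comparison subset (overrides the
#'   random draw; useful for calibration checks).
#' @param seed Optional seed for the random subset.
#' @return Data frame with one row per task: mean rates, t statistic,
#'   degrees of freedom and corrected p-value.
#' @export
sleep_firing_comparison <- function(spike_log, task_sets, layer = 1L,
                                    n_random = 100L,
                                    alternative = c("greater", "two.sided"),
                                    var_equal = TRUE,
                                    n_comparisons = length(task_sets),
                                    random_set = NULL, seed = NULL) {
  alternative <- match.arg(alternative)
  if (is.null(spike_log)) stop("empty spike log")
  rates <- colMeans(spike_log[[layer + 1L]])
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(task_sets), function(task) {
    idx <- task_sets[[task]][[layer]]
    rand <- if (is.null(random_set)) sample(seq_along(rates), n_random)
            else random_set
    if (stats::sd(rates[idx]) == 0 && stats::sd(rates[rand]) == 0) {
      # degenerate: no rate variability in either group
      d <- mean(rates[idx]) - mean(rates[rand])
      tstat <- if (d == 0) 0 else sign(d) * Inf
      dof <- NA_real_
      pval <- if (d > 0) 0 else 1
    } else {
      tt <- stats::t.test(rates[idx], rates[rand], alternative = alternative,
                          var.equal = var_equal)
      tstat <- unname(tt$statistic); dof <- unname(tt$parameter)
      pval <- min(1, tt$p.value * n_comparisons)
    }
    data.frame(task = task, layer = layer,
               rate_task = mean(rates[idx]), rate_random = mean(rates[rand]),
               t = tstat, df = dof, p_value = pval)
  })
  do.call(rbind, rows)
}

#' Change in mean synaptic input drive to a neuron set
#'
#' Mean pre-activation (input drive) of each neuron in the set over the
#' given inputs, before vs. after a sleep phase. An increase for old-task
#' neurons with a decrease for recent-task neurons is the signature of
#' consolidation rebalancing.
#'
#' @param net_before,net_after `dense_net`s of identical architecture.
#' @param x Inputs over which drive is averaged.
#' @param layer Target layer (1 = first hidden; the output layer is
#'   `length(weights)`).
#' @param neuron_set Indices of neurons in that layer.
#' @return Data frame with per-neuron drive before, after and delta.
#' @export
drive_change <- function(net_before, net_after, x, layer, neuron_set) {
  if (!identical(net_before$layer_sizes, net_after$layer_sizes))
    stop("mismatched architectures")
  drive <- function(net) {
    fwd <- forward_wake(net, x)
    colMeans(fwd$preactivations[[layer]][, neuron_set, drop = FALSE])
  }
  before <- drive(net_before); after <- drive(net_after)
  data.frame(neuron = neuron_set, before = before, after = after,
             delta = after - before)
}

#' Toy-model weight histograms by pixel category
#'
#' Partitions the input-to-output weights of a binary-patch network by the
#' category of the source pixel (unique to task 1, unique to task 2, or
#' overlapping) and the task of the destination output neuron. The
#' partition is exact: category counts sum to the number of on-pixels times
#' the outputs considered.
#'
#' @param net The toy `dense_net` (input and output layer only).
#' @param patches The [generate_patches()] object the network was trained
#'   on.
#' @return Data frame with columns `pixel_category`, `to_task`, `weight`
#'   (one row per weight).
#' @export
weight_category_histograms <- function(net, patches) {
  if (length(net$weights) != 1L)
    stop("toy weight histograms require a network with no hidden layers")
  w <- net$weights[[1L]]
  if (ncol(w) != length(patches$categories))
    stop("network input size does not match the patch specification")
  cats <- c("unique_t1", "unique_t2", "overlap")
  rows <- list()
  for (cat in cats) {
    pix <- which(patches$categories == cat)
    if (length(pix) == 0L) next
    for (task in 1:2) {
      outs <- patches$tasks[[task]] + 1L
      vals <- as.vector(w[outs, pix, drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        pixel_category = cat, to_task = task, weight = vals)
    }
  }
  do.call(rbind, rows)
}

#' Cosine similarity between two weight collections
#'
#' Flattens and concatenates all layers of each collection and returns the
#' cosine of the two resulting vectors. A positive value after sequential
#' training indicates that information about the earlier task survives in
#' the weights even when its classification accuracy is lost.
#'
#' @param weights_a,weights_b Lists of weight matrices with equal shapes
#'   (or `dense_net`s, whose weights are used).
#' @return Scalar in `[-1, 1]`, `NA` if either vector is all-zero.
#' @export
weight_cosine_similarity <- function(weights_a, weights_b) {
  if (inherits(weights_a, "dense_net")) weights_a <- weights_a$weights
  if (inherits(weights_b, "dense_net")) weights_b <- weights_b$weights
  if (length(weights_a) != length(weights_b) ||
      !all(mapply(function(a, b) identical(dim(a), dim(b)),
                  weights_a, weights_b)))
    stop("weight collections have mismatched shapes")
  a <- unlist(lapply(weights_a, as.vector))
  b <- unlist(lapply(weights_b, as.vector))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("cosine similarity undefined for a zero weight vector")
    return(NA_real_)
  }
  sum(a * b) / (na * nb)
}

#' Representational sparseness of hidden activations
#'
#' Two measures per stimulus, averaged over stimuli: the fraction of
#' neurons with activation below `tol` (inactive fraction), and the
#' Treves-Rolls population sparseness
#' `(mean a)^2 / mean(a^2)` (lower = sparser).
#'
#' @param net A `dense_net` in wake mode.
#' @param x Stimuli, one per row.
#' @param layer Hidden layer index.
#' @param tol Activation threshold below which a neuron counts as silent.
#' @return List with `inactive_fraction` and `treves_rolls`.
#' @export
activation_sparseness <- function(net, x, layer = 1L, tol = 1e-6) {
  fwd <- forward_wake(net, x)
  a <- fwd$activations[[layer + 1L]]
  inact <- mean(rowMeans(a < tol))
  tr <- mean(apply(a, 1L, function(r) {
    if (all(r == 0)) return(0)
    mean(r)^2 / mean(r^2)
  }))
  list(inactive_fraction = inact, treves_rolls = tr)
}
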