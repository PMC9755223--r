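#' Training hyperparameters for wake (supervised) training
#'
#' Defaults correspond to the fully connected MNIST-class setup: two hidden
#' layers trained by mini-batch stochastic gradient descent with momentum and
#' inverted dropout on the hidden layers, weights initialised uniformly in
#' `[-init_range, init_range]`, and no bias terms anywhere.
#'
#' @param learning_rate Positive step size. May be a vector with one entry per
#'   task for protocols that anneal the rate between tasks.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param epochs_per_task Number of passes over a task's training data.
#' @param batch_size Mini-batch size.
#' @param dropout_rate Probability of dropping a hidden unit during training.
#' @param init_range Half-width of the uniform weight initialisation.
#' @param seed Optional integer seed used by [init_network()] and
#'   [train_task()] for reproducible initialisation, shuffling and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.065, momentum = 0.5,
                            epochs_per_task = 10, batch_size = 100,
                            dropout_rate = 0.2, init_range = 0.02,
                            seed = NULL) {
  stopifnot(all(learning_rate > 0), momentum >= 0, momentum < 1,
            epochs_per_task >= 0, batch_size >= 1,
            dropout_rate >= 0, dropout_rate < 1, init_range >= 0)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs_per_task = as.integer(epochs_per_task),
                 batch_size = as.integer(batch_size),
                 dropout_rate = dropout_rate, init_range = init_range,
                 seed = seed),
            class = "training_config")
}

#' Initialise a bias-free dense network
#'
#' Creates a fully connected feed-forward network with rectifier (ReLU)
#' hidden units and a linear output layer read through softmax cross-entropy.
#' The network carries no bias parameters; `weights[[l]]` has shape
#' `(layer_sizes[l+1], layer_sizes[l])` and maps activations of layer `l` to
#' pre-activations of layer `l+1`. Entries are drawn i.i.d. uniform in
#' `[-init_range, init_range]`.
#'
#' @param layer_sizes Integer vector of at least two positive entries:
#'   input size, hidden sizes..., number of classes.
#' @param config A [training_config()]; supplies `init_range` and `seed`.
#' @return An object of class `dense_net` with fields `layer_sizes`,
#'   `weights` and `mode` (always `"wake"` for a fresh network).
#' @export
init_network <- function(layer_sizes, config = training_config()) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || any(layer_sizes <= 0) || anyNA(layer_sizes))
    stop("invalid architecture: 'layer_sizes' needs >= 2 positive entries")
  if (!is.null(config$seed)) set.seed(config$seed)
  n_layers <- length(layer_sizes)
  weights <- vector("list", n_layers - 1L)
  for (l in seq_len(n_layers - 1L)) {
    weights[[l]] <- matrix(
      stats::runif(layer_sizes[l + 1L] * layer_sizes[l],
                   min = -config$init_range, max = config$init_range),
      nrow = layer_sizes[l + 1L], ncol = layer_sizes[l])
  }
  structure(list(layer_sizes = layer_sizes, weights = weights, mode = "wake"),
            class = "dense_net")
}

#' @export
print.dense_net <- function(x, ...) {
  cat("Bias-free dense network (", x$mode, " mode): ",
      paste(x$layer_sizes, collapse = "-"), "\n", sep = "")
  invisible(x)
}

n_weight_layers <- function(net) length(net$weights)

check_data <- function(net, x, y = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != net$layer_sizes[1L])
    stop("input dimension ", ncol(x), " does not match network input size ",
         net$layer_sizes[1L])
  if (!is.null(y)) {
    y <- as.integer(y)
    k <- net$layer_sizes[length(net$layer_sizes)]
    if (length(y) != nrow(x)) stop("label/image count mismatch")
    if (any(y < 0L) || any(y >= k))
      stop("label outside output-layer range [0, ", k - 1L, "]")
  }
  list(x = x, y = y)
}

#' Wake-mode forward pass
#'
#' Propagates a batch through the network with rectifier hidden units and raw
#' logits at the output. Used internally by training and evaluation; exposed
#' for diagnostics (per-layer activations and pre-activations).
#'
#' @param net A `dense_net` in wake mode.
#' @param x Numeric matrix, one sample per row.
#' @param dropout_masks Optional list of per-hidden-layer multiplicative
#'   masks (inverted dropout), as built during training.
#' @return List with `activations` (per layer, the input counted as layer 1)
#'   and `preactivations` (per weight layer).
#' @export
forward_wake <- function(net, x, dropout_masks = NULL) {
  x <- check_data(net, x)$x
  L <- n_weight_layers(net)
  acts <- vector("list", L + 1L)
  pre <- vector("list", L)
  acts[[1L]] <- x
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% t(net$weights[[l]])
    pre[[l]] <- z
    if (l < L) {
      a <- pmax(z, 0)
      if (!is.null(dropout_masks) && !is.null(dropout_masks[[l]]))
        a <- a * dropout_masks[[l]]
      acts[[l + 1L]] <- a
    } else {
      acts[[l + 1L]] <- z   # raw logits
    }
  }
  list(activations = acts, preactivations = pre)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

cross_entropy <- function(logits, y) {
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(nrow(p)), y + 1L)
  -mean(log(pmax(p[idx], 1e-300)))
}

# One backward pass; sample_weights are per-sample loss weights that must sum
# to the effective "mean" normalisation (plain CE uses 1/n each).
backprop <- function(net, fwd, y, sample_weights) {
  L <- n_weight_layers(net)
  logits <- fwd$activations[[L + 1L]]
  p <- softmax_rows(logits)
  delta <- p
  idx <- cbind(seq_len(nrow(p)), y + 1L)
  delta[idx] <- delta[idx] - 1
  delta <- delta * sample_weights
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- t(delta) %*% fwd$activations[[l]]
    if (l > 1L) {
      delta <- delta %*% net$weights[[l]]
      delta <- delta * (fwd$preactivations[[l - 1L]] > 0)
      # the stored activation already includes the dropout mask; gradients
      # must too, which the mask-on-activation formulation handles because a
      # dropped unit has activation 0 and its rectifier gate passes nothing
      # only when the mask is re-applied:
      if (!is.null(fwd$dropout_masks) && !is.null(fwd$dropout_masks[[l - 1L]]))
        delta <- delta * fwd$dropout_masks[[l - 1L]]
    }
  }
  grads
}

sgd_step <- function(net, velocity, grads, lr, momentum) {
  for (l in seq_along(net$weights)) {
    velocity[[l]] <- momentum * velocity[[l]] - lr * grads[[l]]
    net$weights[[l]] <- net$weights[[l]] + velocity[[l]]
  }
  list(net = net, velocity = velocity)
}

zero_like_weights <- function(net)
  lapply(net$weights, function(w) array(0, dim(w)))

make_dropout_masks <- function(net, n, rate) {
  if (rate <= 0) return(NULL)
  L <- n_weight_layers(net)
  masks <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    width <- net$layer_sizes[l + 1L]
    keep <- matrix(stats::runif(n * width) >= rate, nrow = n)
    masks[[l]] <- keep / (1 - rate)
  }
  masks
}

#' Train the network on one task
#'
#' Mini-batch stochastic gradient descent with momentum on the softmax
#' cross-entropy of the presented samples only (class-incremental wake
#' training: the loss never sees absent classes). Labels are global class
#' indices into the single shared output head. Inverted dropout is applied to
#' hidden activations during training and disabled everywhere else.
#'
#' @param net A `dense_net` in wake mode.
#' @param x Numeric matrix of inputs in `[0, 1]`, one sample per row.
#' @param y Integer vector of 0-based global class labels.
#' @param config A [training_config()].
#' @param learning_rate Optional override of `config$learning_rate` (used by
#'   protocols with per-task rates).
#' @return The trained `dense_net`.
#' @export
train_task <- function(net, x, y, config = training_config(),
                       learning_rate = NULL) {
  d <- check_data(net, x, y)
  x <- d$x; y <- d$y
  lr <- if (is.null(learning_rate)) config$learning_rate[1L] else learning_rate
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$epochs_per_task == 0L) return(net)
  velocity <- zero_like_weights(net)
  n <- nrow(x)
  for (epoch in seq_len(config$epochs_per_task)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      take <- perm[s:min(s + config$batch_size - 1L, n)]
      xb <- x[take, , drop = FALSE]
      yb <- y[take]
      masks <- make_dropout_masks(net, length(take), config$dropout_rate)
      fwd <- forward_wake(net, xb, masks)
      fwd$dropout_masks <- masks
      grads <- backprop(net, fwd, yb, rep(1 / length(take), length(take)))
      step <- sgd_step(net, velocity, grads, lr, config$momentum)
      net <- step$net; velocity <- step$velocity
    }
  }
  net
}

#' Full-batch training to convergence (toy tasks)
#'
#' Trains a softmax classifier by full-batch gradient descent with no
#' momentum and no dropout until the cross-entropy loss plateaus (change
#' below `tol`) or `max_epochs` is reached. Used for the binary-patch toy
#' task, whose networks have no hidden layer.
#'
#' @param net A `dense_net`.
#' @param x,y Training data as in [train_task()].
#' @param learning_rate Step size.
#' @param tol Loss-plateau tolerance.
#' @param max_epochs Epoch cap.
#' @return The trained `dense_net`.
#' @export
train_to_convergence <- function(net, x, y, learning_rate = 0.1,
                                 tol = 1e-5, max_epochs = 500L) {
  d <- check_data(net, x, y)
  x <- d$x; y <- d$y
  velocity <- zero_like_weights(net)
  last <- Inf
  for (epoch in seq_len(max_epochs)) {
    fwd <- forward_wake(net, x)
    loss <- cross_entropy(fwd$activations[[length(fwd$activations)]], y)
    if (abs(last - loss) < tol) break
    last <- loss
    grads <- backprop(net, fwd, y, rep(1 / nrow(x), nrow(x)))
    step <- sgd_step(net, velocity, grads, learning_rate, 0)
    net <- step$net; velocity <- step$velocity
  }
  net
}

#' Evaluate classification accuracy
#'
#' Computes the fraction of samples whose argmax logit equals the true global
#' label, with argmax ties broken deterministically by the lowest class
#' index. Dropout is never applied at evaluation.
#'
#' @param net A `dense_net` in wake mode.
#' @param x,y Evaluation data (labels 0-based).
#' @param task_classes Optional list mapping task id to the integer class
#'   labels it contains; adds a per-task accuracy breakdown.
#' @return An object of class `src_eval`: list with `accuracy`, `predicted`,
#'   `per_class` (data frame class/n/accuracy) and, when `task_classes` is
#'   given, `per_task`.
#' @export
evaluate <- function(net, x, y, task_classes = NULL) {
  d <- check_data(net, x, y)
  x <- d$x; y <- d$y
  if (nrow(x) == 0L) stop("accuracy is undefined on an empty dataset")
  fwd <- forward_wake(net, x)
  logits <- fwd$activations[[length(fwd$activations)]]
  pred <- max.col(logits, ties.method = "first") - 1L
  acc <- mean(pred == y)
  classes <- sort(unique(y))
  per_class <- data.frame(
    class = classes,
    n = vapply(classes, function(k) sum(y == k), integer(1)),
    accuracy = vapply(classes, function(k) mean(pred[y == k] == y[y == k]),
                      numeric(1)))
  out <- list(accuracy = acc, predicted = pred, per_class = per_class)
  if (!is.null(task_classes)) {
    out$per_task <- data.frame(
      task_id = seq_along(task_classes),
      accuracy = vapply(task_classes, function(cls) {
        sel <- y %in% cls
        if (!any(sel)) return(NA_real_)
        mean(pred[sel] == y[sel])
      }, numeric(1)))
  }
  class(out) <- "src_eval"
  out
}

#' @export
print.src_eval <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.4f (n = %d)\n",
              x$accuracy, length(x$predicted)))
  invisible(x)
}
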