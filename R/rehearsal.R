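#' Rehearsal settings and the task-weighted loss
#'
#' A small fraction of each finished task's training examples is stored with
#' hard labels and mixed into later training. To promote quick recovery of
#' old tasks the loss is reweighted by task count: with `N` tasks seen the
#' current task contributes weight `1/N` and the stored old data `1 - 1/N`,
#' so the two weights always sum to one.
#'
#' @param fraction_stored Per-class fraction of old-task examples retained.
#' @param n_tasks_seen Number of tasks seen so far (including the current).
#' @return An object of class `rehearsal_config` with derived fields
#'   `loss_weight_current` and `loss_weight_old`.
#' @export
rehearsal_config <- function(fraction_stored = 0.0075, n_tasks_seen = 1L) {
  stopifnot(fraction_stored >= 0, fraction_stored <= 1, n_tasks_seen >= 1)
  n <- as.integer(n_tasks_seen)
  structure(list(fraction_stored = fraction_stored,
                 n_tasks_seen = n,
                 loss_weight_current = 1 / n,
                 loss_weight_old = 1 - 1 / n),
            class = "rehearsal_config")
}

#' Add a finished task's examples to the rehearsal buffer
#'
#' Stores a per-class uniform random sample (without replacement) of the
#' task's training examples together with their hard labels. With 5000
#' images per task and `fraction_stored = 0.02`, 100 random images are kept.
#'
#' @param buffer Existing buffer (list with `x`, `y`) or `NULL`.
#' @param x,y The finished task's training data.
#' @param fraction_stored Fraction of examples to keep per class.
#' @return Updated buffer: list with matrix `x` and integer vector `y`.
#' @export
update_rehearsal_buffer <- function(buffer, x, y, fraction_stored) {
  x <- as.matrix(x); y <- as.integer(y)
  keep <- integer(0)
  for (k in sort(unique(y))) {
    idx <- which(y == k)
    n_keep <- round(length(idx) * fraction_stored)
    if (n_keep > 0)
      keep <- c(keep, sample(idx, n_keep))
  }
  new_x <- x[keep, , drop = FALSE]
  new_y <- y[keep]
  if (is.null(buffer))
    list(x = new_x, y = new_y)
  else
    list(x = rbind(buffer$x, new_x), y = c(buffer$y, new_y))
}

#' Train on a task with rehearsal of stored old examples
#'
#' Each mini-batch is drawn from the union of the current task's data and the
#' rehearsal buffer. The step minimises
#' `loss_weight_current * mean CE(current samples in batch) +
#'  loss_weight_old * mean CE(old samples in batch)`;
#' a batch that happens to contain no old samples contributes no old-task
#' term. With one task seen the weights are 1 and 0 and the call reduces to
#' plain training.
#'
#' @param net A `dense_net` in wake mode.
#' @param x,y Current-task training data (labels 0-based, global head).
#' @param buffer Rehearsal buffer from [update_rehearsal_buffer()], or `NULL`.
#' @param rehearsal A [rehearsal_config()] (supplies the loss weights).
#' @param config A [training_config()].
#' @param learning_rate Optional per-task learning-rate override.
#' @return The trained `dense_net`.
#' @export
train_task_with_rehearsal <- function(net, x, y, buffer,
                                      rehearsal = rehearsal_config(),
                                      config = training_config(),
                                      learning_rate = NULL) {
  d <- check_data(net, x, y)
  x <- d$x; y <- d$y
  no_old <- is.null(buffer) || length(buffer$y) == 0L
  if (no_old && rehearsal$n_tasks_seen > 1L)
    warning("empty rehearsal buffer with n_tasks_seen > 1; ",
            "falling back to current-task loss")
  if (no_old || rehearsal$loss_weight_old == 0)
    return(train_task(net, x, y, config, learning_rate))
  check_data(net, buffer$x, buffer$y)
  lr <- if (is.null(learning_rate)) config$learning_rate[1L] else learning_rate
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$epochs_per_task == 0L) return(net)

  all_x <- rbind(x, buffer$x)
  all_y <- c(y, buffer$y)
  is_old <- c(rep(FALSE, length(y)), rep(TRUE, length(buffer$y)))
  w_cur <- rehearsal$loss_weight_current
  w_old <- rehearsal$loss_weight_old
  velocity <- zero_like_weights(net)
  n <- nrow(all_x)
  for (epoch in seq_len(config$epochs_per_task)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      take <- perm[s:min(s + config$batch_size - 1L, n)]
      old_b <- is_old[take]
      sw <- numeric(length(take))
      n_cur <- sum(!old_b); n_old <- sum(old_b)
      if (n_cur > 0) sw[!old_b] <- w_cur / n_cur
      if (n_old > 0) sw[old_b] <- w_old / n_old
      masks <- make_dropout_masks(net, length(take), config$dropout_rate)
      fwd <- forward_wake(net, all_x[take, , drop = FALSE], masks)
      fwd$dropout_masks <- masks
      grads <- backprop(net, fwd, all_y[take], sw)
      step <- sgd_step(net, velocity, grads, lr, config$momentum)
      net <- step$net; velocity <- step$velocity
    }
  }
  net
}
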