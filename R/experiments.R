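eval_phase_rows <- function(net, stream, phase) {
  test <- stream$test
  ev <- evaluate(net, test$x, test$y)
  if (!is.null(stream$test_task)) {
    per_task <- vapply(seq_along(stream$tasks), function(i) {
      sel <- stream$test_task == i
      mean(ev$predicted[sel] == test$y[sel])
    }, numeric(1))
  } else {
    per_task <- vapply(stream$task_classes, function(cls) {
      sel <- test$y %in% cls
      mean(ev$predicted[sel] == test$y[sel])
    }, numeric(1))
  }
  rbind(
    data.frame(phase = phase, task_id = as.character(seq_along(per_task)),
               accuracy = per_task),
    data.frame(phase = phase, task_id = "overall", accuracy = ev$accuracy))
}

run_stream <- function(stream, layer_sizes, config,
                       sleep_cfg = NULL, rehearsal_fraction = NULL,
                       tune = FALSE, tune_args = list(),
                       keep_nets = FALSE, keep_spike_logs = FALSE) {
  net <- init_network(layer_sizes, config)
  stats <- new_input_statistics(layer_sizes[1L])
  buffer <- NULL
  seen_x <- NULL; seen_y <- NULL
  rows <- list(); nets <- list(); logs <- list()
  tuned_cfg <- sleep_cfg
  cfg_inner <- config
  cfg_inner$seed <- NULL   # the init seed must not re-seed every task
  for (i in seq_along(stream$tasks)) {
    task <- stream$tasks[[i]]
    lr <- config$learning_rate[min(i, length(config$learning_rate))]
    if (!is.null(rehearsal_fraction) && i > 1L) {
      reh <- rehearsal_config(rehearsal_fraction, n_tasks_seen = i)
      net <- train_task_with_rehearsal(net, task$x, task$y, buffer, reh,
                                       cfg_inner, learning_rate = lr)
    } else {
      net <- train_task(net, task$x, task$y, cfg_inner, learning_rate = lr)
    }
    stats <- update_input_statistics(stats, task$x)
    seen_x <- rbind(seen_x, task$x); seen_y <- c(seen_y, task$y)
    rows[[length(rows) + 1L]] <- eval_phase_rows(net, stream, paste0("T", i))
    if (keep_nets) nets[[paste0("T", i)]] <- net
    if (!is.null(sleep_cfg)) {
      if (isTRUE(tune)) {
        tn <- do.call(tune_sleep, c(list(net = net, stats = stats,
                                         train_x = seen_x, train_y = seen_y,
                                         reference_data = task$x,
                                         base = sleep_cfg,
                                         duration = sleep_cfg$duration),
                                    tune_args))
        tuned_cfg <- tn$config
      }
      scfg <- tuned_cfg
      scfg$keep_spike_log <- keep_spike_logs
      res <- sleep_replay(net, stats, scfg, reference_data = task$x)
      net <- res$net
      if (keep_spike_logs) logs[[paste0("S", i)]] <- res$spike_log
      rows[[length(rows) + 1L]] <- eval_phase_rows(net, stream,
                                                   paste0("S", i))
      if (keep_nets) nets[[paste0("S", i)]] <- net
    }
    if (!is.null(rehearsal_fraction))
      buffer <- update_rehearsal_buffer(buffer, task$x, task$y,
                                        rehearsal_fraction)
  }
  out <- list(table = do.call(rbind, rows), net = net, stats = stats,
              sleep_config = tuned_cfg)
  if (keep_nets) out$nets <- nets
  if (keep_spike_logs) out$spike_logs <- logs
  out
}

#' Sequential (no-sleep) class-incremental baseline
#'
#' Trains the tasks of a stream in order with a single shared output head
#' and records the full per-task accuracy table after every training phase.
#' This is the catastrophic-forgetting lower bound against which the sleep
#' protocol is compared.
#'
#' @param stream A [build_task_stream()] object.
#' @param layer_sizes Full architecture (input, hidden..., classes).
#' @param config A [training_config()]; its `seed` controls initialisation
#'   and batch shuffling of the whole run.
#' @param ... Passed to the internal engine (e.g. `keep_nets = TRUE` to
#'   retain the network snapshot after every phase).
#' @return List with `table` (data frame: phase, task_id, accuracy; task_id
#'   `"overall"` rows give the all-class accuracy), `net` and `stats`.
#' @export
run_sequential <- function(stream, layer_sizes, config = training_config(),
                           ...) {
  run_stream(stream, layer_sizes, config, sleep_cfg = NULL, ...)
}

#' Class-incremental training with sleep replay after every task
#'
#' As [run_sequential()] but inserts a sleep replay consolidation episode
#' after each task's training, using the running mean input statistics and
#' the current task's training inputs as normalisation reference. With
#' `tune = TRUE` the sleep hyperparameters are re-searched after each task
#' against the training data seen so far.
#'
#' @inheritParams run_sequential
#' @param sleep_cfg A [sleep_config()].
#' @param tune Re-tune sleep hyperparameters each task via [tune_sleep()].
#' @param tune_args Extra arguments (candidate grids) for [tune_sleep()].
#' @param keep_spike_logs Retain per-episode spike logs for replay analysis.
#' @return As [run_sequential()], with sleep phases (`S1`, `S2`, ...)
#'   interleaved in `table`, plus the `sleep_config` actually used.
#' @export
run_src_protocol <- function(stream, layer_sizes, config = training_config(),
                             sleep_cfg = sleep_config(), tune = FALSE,
                             tune_args = list(), keep_spike_logs = FALSE,
                             ...) {
  run_stream(stream, layer_sizes, config, sleep_cfg = sleep_cfg,
             tune = tune, tune_args = tune_args,
             keep_spike_logs = keep_spike_logs, ...)
}

#' Rehearsal protocol, optionally combined with sleep replay
#'
#' Stores a fraction of each finished task's examples and mixes them into
#' later training under the task-weighted loss; optionally runs a sleep
#' episode after each task as well.
#'
#' @inheritParams run_src_protocol
#' @param fraction_stored Per-class fraction of old examples retained.
#' @param with_src Insert a sleep phase after each task.
#' @return As [run_sequential()].
#' @export
run_rehearsal_protocol <- function(stream, layer_sizes,
                                   config = training_config(),
                                   fraction_stored = 0.0075,
                                   with_src = FALSE,
                                   sleep_cfg = sleep_config(), tune = FALSE,
                                   tune_args = list(), ...) {
  run_stream(stream, layer_sizes, config,
             sleep_cfg = if (with_src) sleep_cfg else NULL,
             rehearsal_fraction = fraction_stored,
             tune = tune, tune_args = tune_args, ...)
}

#' Single-task undertraining probe
#'
#' Trains a fresh network on one task for a varying number of epochs and
#' measures accuracy before and after a sleep episode. Sleep is expected to
#' help undertrained networks and to be neutral or slightly harmful once
#' the task is well learned.
#'
#' @param x,y Training data of the single task.
#' @param test List with `x`, `y` test data.
#' @param layer_sizes Full architecture.
#' @param epochs_grid Integer vector of training amounts to probe.
#' @param config A [training_config()] (its `epochs_per_task` is overridden
#'   by the grid).
#' @param sleep_cfg A [sleep_config()].
#' @param tune Re-tune sleep hyperparameters per training amount (on the
#'   training data) via [tune_sleep()].
#' @param tune_args Candidate grids for [tune_sleep()].
#' @return Data frame: epochs, accuracy_pre, accuracy_post.
#' @export
run_single_task_probe <- function(x, y, test, layer_sizes,
                                  epochs_grid = c(0L, 1L, 10L),
                                  config = training_config(),
                                  sleep_cfg = sleep_config(),
                                  tune = FALSE, tune_args = list()) {
  stats0 <- update_input_statistics(new_input_statistics(ncol(x)), x)
  rows <- lapply(epochs_grid, function(e) {
    cfg <- config
    cfg$epochs_per_task <- as.integer(e)
    net <- init_network(layer_sizes, cfg)
    net <- train_task(net, x, y, cfg)
    pre <- evaluate(net, test$x, test$y)$accuracy
    scfg <- sleep_cfg
    if (isTRUE(tune)) {
      tn <- do.call(tune_sleep, c(list(net = net, stats = stats0,
                                       train_x = x, train_y = y,
                                       base = sleep_cfg,
                                       duration = sleep_cfg$duration),
                                  tune_args))
      scfg <- tn$config
    }
    res <- sleep_replay(net, stats0, scfg, reference_data = x)
    post <- evaluate(res$net, test$x, test$y)$accuracy
    data.frame(epochs = e, accuracy_pre = pre, accuracy_post = post)
  })
  do.call(rbind, rows)
}

#' Run the binary-patch toy experiment
#'
#' Trains the no-hidden-layer softmax network on task 1 (images 0, 1), then
#' task 2 (images 2, 3), each by full-batch gradient descent to
#' convergence, and optionally applies sleep replay afterwards. Accuracy is
#' always measured over all four images.
#'
#' @param overlap Cross-task pixel overlap of the patches.
#' @param seed Integer seed (patch layout, initialisation, sleep noise).
#' @param sleep_cfg Optional [sleep_config()]; `NULL` skips the sleep phase.
#' @param tune Tune sleep hyperparameters on the four training images.
#' @param tune_args Candidate grids for [tune_sleep()].
#' @param learning_rate,tol,max_epochs Toy-trainer settings.
#' @return List with `table` (phase T1/T2/SRC accuracy rows), `net`,
#'   `nets` (snapshot per phase), `patches` and `stats`.
#' @export
run_patches_experiment <- function(overlap, seed = 1L, sleep_cfg = NULL,
                                   tune = FALSE, tune_args = list(),
                                   learning_rate = 0.1, tol = 1e-5,
                                   max_epochs = 500L) {
  patches <- generate_patches(overlap = overlap, seed = seed)
  stream <- build_task_stream(patches, protocol = "patches")
  cfg <- training_config(momentum = 0, dropout_rate = 0,
                         init_range = 0.02, seed = seed)
  net <- init_network(c(ncol(patches$x), 4L), cfg)
  stats <- new_input_statistics(ncol(patches$x))
  rows <- list(); nets <- list()
  for (i in 1:2) {
    task <- stream$tasks[[i]]
    net <- train_to_convergence(net, task$x, task$y, learning_rate,
                                tol, max_epochs)
    stats <- update_input_statistics(stats, task$x)
    rows[[i]] <- eval_phase_rows(net, stream, paste0("T", i))
    nets[[paste0("T", i)]] <- net
  }
  scfg <- sleep_cfg
  if (!is.null(sleep_cfg)) {
    if (isTRUE(tune)) {
      tn <- do.call(tune_sleep,
                    c(list(net = net, stats = stats,
                           train_x = patches$x, train_y = patches$y,
                           reference_data = stream$tasks[[2L]]$x,
                           base = sleep_cfg, duration = sleep_cfg$duration,
                           seed = seed),
                      tune_args))
      scfg <- tn$config
    }
    scfg$seed <- seed
    res <- sleep_replay(net, stats, scfg,
                        reference_data = stream$tasks[[2L]]$x)
    net <- res$net
    rows[[3L]] <- eval_phase_rows(net, stream, "SRC")
    nets[["SRC"]] <- net
  }
  list(table = do.call(rbind, rows), net = net, nets = nets,
       patches = patches, stats = stats, sleep_config = scfg)
}

#' Sweep the toy experiment over pixel overlaps and seeds
#'
#' @param overlaps Integer vector of overlap values.
#' @param seeds Integer vector of seeds per overlap.
#' @param ... Passed to [run_patches_experiment()] (e.g. `sleep_cfg`,
#'   `tune = TRUE`).
#' @return Data frame: overlap, seed, phase, accuracy (overall accuracy
#'   over the four images after each phase).
#' @export
run_patches_sweep <- function(overlaps, seeds = 1:5, ...) {
  rows <- list()
  for (ov in overlaps) for (s in seeds) {
    res <- run_patches_experiment(overlap = ov, seed = s, ...)
    tab <- res$table
    tab <- tab[tab$task_id == "overall", c("phase", "accuracy")]
    rows[[length(rows) + 1L]] <- cbind(overlap = ov, seed = s, tab)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a run's accuracy table and manifest to disk
#'
#' Emits the per-phase accuracy table as CSV (columns phase, task_id,
#' accuracy) and a JSON manifest of the run settings.
#'
#' @param result A result list from one of the `run_*` functions.
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return Invisibly, the paths written.
#' @export
write_run_outputs <- function(result, dir, name = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, "_accuracy.csv"))
  utils::write.csv(result$table, csv, row.names = FALSE)
  manifest <- file.path(dir, paste0(name, "_manifest.json"))
  cfg <- result$sleep_config
  jsonlite::write_json(
    list(phases = unique(result$table$phase),
         final_overall = utils::tail(
           result$table$accuracy[result$table$task_id == "overall"], 1L),
         sleep_config = if (is.null(cfg)) NULL else
           cfg[c("duration", "inc", "dec", "thresholds",
                 "scale_multiplier", "input_mode")]),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, manifest))
}
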