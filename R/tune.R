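#' Grid search over sleep hyperparameters
#'
#' Spike thresholds, scale multipliers and Hebbian magnitudes are
#' task-dependent; the reference procedure selects them by maximising
#' accuracy on the training data seen so far after a trial sleep episode.
#' This utility evaluates every combination of the supplied candidate
#' values (scalar thresholds/multipliers are recycled across layers) and
#' returns the best configuration together with the score table.
#'
#' @param net The trained `dense_net` to be slept.
#' @param stats Populated `input_stats`.
#' @param train_x,train_y All training data seen so far (scoring set).
#' @param reference_data Inputs for layer normalisation (defaults to
#'   `train_x`).
#' @param thresholds,scale_multipliers,inc,dec Candidate values; every
#'   combination is tried. The plasticity magnitudes default to the base
#'   configuration's values, so the default search covers thresholds and
#'   scale multipliers only.
#' @param duration Sleep duration used during the search.
#' @param base A [sleep_config()] supplying the remaining settings.
#' @param seed Seed for the trial sleep episodes (one shared seed keeps the
#'   comparison paired across candidates).
#' @return List with `config` (best [sleep_config()]), `score` (its
#'   training accuracy) and `results` (data frame of all candidates).
#' @export
tune_sleep <- function(net, stats, train_x, train_y,
                       reference_data = train_x,
                       thresholds = c(0.5, 1, 2, 4),
                       scale_multipliers = c(1, 2, 4),
                       inc = base$inc, dec = base$dec,
                       duration = 1000L, base = sleep_config(),
                       seed = 1L) {
  grid <- expand.grid(threshold = thresholds, mult = scale_multipliers,
                      inc = inc, dec = dec, KEEP.OUT.ATTRS = FALSE)
  grid$score <- NA_real_
  best <- NULL; best_score <- -Inf
  for (i in seq_len(nrow(grid))) {
    cfg <- base
    cfg$duration <- as.integer(duration)
    cfg$thresholds <- grid$threshold[i]
    cfg$scale_multiplier <- grid$mult[i]
    cfg$inc <- grid$inc[i]
    cfg$dec <- grid$dec[i]
    cfg$keep_spike_log <- FALSE
    cfg$seed <- seed
    res <- sleep_replay(net, stats, cfg, reference_data)
    grid$score[i] <- evaluate(res$net, train_x, train_y)$accuracy
    if (grid$score[i] > best_score) {
      best_score <- grid$score[i]
      best <- cfg
    }
  }
  list(config = best, score = best_score, results = grid)
}
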