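#' Define the staged training-and-reduction schedule
#'
#' The default schedule reproduces the full 13,500-epoch protocol: 5,000
#' epochs of plain training, then three weight-decay iterations (1,000
#' epochs with decay, deletion of small weights, 1,000 epochs without
#' decay), reaching the partially reduced network at epoch 11,000; then a
#' first unit-deletion round (delete inactive units, 1,000 retraining
#' epochs, 500 epochs with decay, delete small weights) and two further
#' rounds (delete inactive units, 500 retraining epochs each), for 13,500
#' epochs in total with checkpoints at 5,000, 11,000 and 13,500.
#'
#' @param initial_epochs plain training epochs before any reduction.
#' @param decay_epochs epochs with weight decay per decay iteration.
#' @param retrain_epochs epochs without decay per decay iteration.
#' @param n_decay_iterations number of decay iterations.
#' @param unit_retrain_epochs retraining epochs after the first unit
#'   deletion.
#' @param unit_decay_epochs decay epochs ending the first unit-deletion
#'   round (followed by small-weight deletion).
#' @param extra_unit_rounds further unit-deletion rounds.
#' @param extra_retrain_epochs retraining epochs per further round.
#' @param weight_delete_threshold magnitude below which weights are removed
#'   at deletion events (default 0.05; the protocol treats it as
#'   adjustable).
#' @param activity_window probe length, in steps, for unit deletion
#'   (default 200).
#' @param activity_floor minimum deletion threshold so that fully silent
#'   units remain removable even when \code{(1 - alpha) / 2} is 0
#'   (default 0.01).
#' @return an object of class \code{sah_reduction_schedule}.
#' @export
reduction_schedule <- function(initial_epochs = 5000L, decay_epochs = 1000L,
                               retrain_epochs = 1000L,
                               n_decay_iterations = 3L,
                               unit_retrain_epochs = 1000L,
                               unit_decay_epochs = 500L,
                               extra_unit_rounds = 2L,
                               extra_retrain_epochs = 500L,
                               weight_delete_threshold = 0.05,
                               activity_window = 200L,
                               activity_floor = 0.01) {
  s <- structure(list(initial_epochs = as.integer(initial_epochs),
                      decay_epochs = as.integer(decay_epochs),
                      retrain_epochs = as.integer(retrain_epochs),
                      n_decay_iterations = as.integer(n_decay_iterations),
                      unit_retrain_epochs = as.integer(unit_retrain_epochs),
                      unit_decay_epochs = as.integer(unit_decay_epochs),
                      extra_unit_rounds = as.integer(extra_unit_rounds),
                      extra_retrain_epochs = as.integer(extra_retrain_epochs),
                      weight_delete_threshold = weight_delete_threshold,
                      activity_window = as.integer(activity_window),
                      activity_floor = activity_floor),
                 class = "sah_reduction_schedule")
  if (any(unlist(s[1:8]) < 0) || weight_delete_threshold < 0)
    stop("schedule quantities must be >= 0", call. = FALSE)
  s
}

# Checkpoint epochs implied by a schedule: end of initial training, end of
# the decay iterations, end of the whole protocol.
schedule_checkpoints <- function(s) {
  cp1 <- s$initial_epochs
  cp2 <- cp1 + s$n_decay_iterations * (s$decay_epochs + s$retrain_epochs)
  cp3 <- cp2 + s$unit_retrain_epochs + s$unit_decay_epochs +
    s$extra_unit_rounds * s$extra_retrain_epochs
  c(unreduced = cp1, partial = cp2, reduced = cp3)
}

#' Total number of training epochs in a schedule
#' @param schedule an \code{sah_reduction_schedule}.
#' @export
schedule_total_epochs <- function(schedule) {
  unname(schedule_checkpoints(schedule)["reduced"])
}

#' Delete small weights
#'
#' Permanently removes from the connection mask every present weight with
#' magnitude strictly below the threshold; the comparison is strict, so a
#' weight exactly at the threshold survives.
#'
#' @param network an \code{sah_network}.
#' @param threshold non-negative deletion threshold.
#' @return the pruned network.
#' @export
delete_small_weights <- function(network, threshold) {
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  drop <- network$mask & abs(network$weights) < threshold
  network$mask[drop] <- FALSE
  network$weights[drop] <- 0
  # re-clip survivors into class bounds (decay may have undercut the minimum)
  b <- bounds_matrices(network)
  W <- pmin(pmax(network$weights, b$lb), b$ub)
  W[!network$mask] <- 0
  network$weights <- W
  network
}

#' Delete inactive hidden units
#'
#' Simulates \code{activity_window} steps of fresh task input and marks as
#' dead every live hidden unit whose peak activity stays below
#' \code{max((1 - alpha) / 2, activity_floor)}. Dead units lose all their
#' connections permanently; input and output units are never deleted.
#'
#' @param network an \code{sah_network}.
#' @param task the task the network was trained on (its \code{alpha} sets
#'   the threshold).
#' @param seed optional seed for the probe episode.
#' @param activity_window probe length in steps (default 200).
#' @param activity_floor minimum threshold (default 0.01).
#' @return the pruned network.
#' @export
delete_inactive_units <- function(network, task, seed = NULL,
                                  activity_window = 200L,
                                  activity_floor = 0.01) {
  probe_cfg <- task_config(alpha = task$alpha,
                           epoch_length = as.integer(activity_window),
                           gate_spacing_min = task$gate_spacing_min,
                           gate_spacing_max = task$gate_spacing_max,
                           target_delay = task$target_delay,
                           n_signals = task$n_signals)
  probe <- generate_episode(probe_cfg, seed = seed)
  trace <- run_episode(network, probe)
  thr <- max((1 - task$alpha) / 2, activity_floor)
  hid <- hidden_idx(network)
  live <- hid[network$alive[hid]]
  peak <- apply(trace[, live, drop = FALSE], 2, max)
  dead <- live[peak < thr]
  if (length(dead)) {
    network$alive[dead] <- FALSE
    network$mask[dead, ] <- FALSE
    network$mask[, dead] <- FALSE
    network$weights[dead, ] <- 0
    network$weights[, dead] <- 0
  }
  network
}

#' Run the full training-and-reduction schedule
#'
#' Executes the staged protocol on a network: initial training, weight-decay
#' iterations with small-weight deletion, and unit-deletion rounds with
#' retraining, recording test error and network size along the way and
#' returning the networks saved at the three checkpoints.
#'
#' @param network a freshly built (or pre-trained) \code{sah_network}.
#' @param task a \code{\link{task_config}}.
#' @param schedule an \code{\link{reduction_schedule}}.
#' @param config a \code{\link{training_config}}.
#' @param seed root seed; expands into independent training, test and probe
#'   streams.
#' @return a list with \code{checkpoints} (networks \code{unreduced},
#'   \code{partial}, \code{reduced}), \code{network} (the final network,
#'   identical to the reduced checkpoint), and \code{history} (data frame
#'   epoch / hidden_units / weights / percent_error, including a row at
#'   epoch 0).
#' @export
run_reduction_schedule <- function(network, task,
                                   schedule = reduction_schedule(),
                                   config = training_config(), seed = NULL) {
  stopifnot(inherits(network, "sah_network"),
            inherits(schedule, "sah_reduction_schedule"))
  cps <- schedule_checkpoints(schedule)
  seeds <- derive_seeds(seed, 3L)
  test <- episodes_to_arrays(task, config$n_test_episodes, seeds[2])
  probe_seeds <- derive_seeds(seeds[3], schedule$extra_unit_rounds + 1L)
  phase_seed <- seeds[1]
  next_phase_seed <- function() {
    phase_seed <<- derive_seeds(phase_seed, 1L)
    phase_seed
  }

  history <- data.frame(epoch = 0L, hidden_units = count_live_units(network),
                        weights = count_weights(network),
                        percent_error = percent_error_on(network, test))
  epoch <- 0L
  state <- new_opt_state(network, config)

  run_block <- function(net, n_epochs, decay) {
    if (n_epochs == 0L) return(net)
    res <- train_phase(net, task, n_epochs, config,
                       if (decay) config$weight_decay_amount else 0,
                       state, test, next_phase_seed(), epoch)
    epoch <<- epoch + n_epochs
    state <<- res$state
    h <- res$history
    if (nrow(h)) {
      h$hidden_units <- count_live_units(res$network)
      h$weights <- count_weights(res$network)
      history <<- rbind(history,
                        h[, c("epoch", "hidden_units", "weights", "percent_error")])
    }
    res$network
  }
  # stored search directions refer to weights that deletion may remove,
  # so the optimizer state is reset at every structural change
  reset_state <- function(net) state <<- new_opt_state(net, config)

  net <- run_block(network, schedule$initial_epochs, decay = FALSE)
  unreduced <- net

  for (it in seq_len(schedule$n_decay_iterations)) {
    net <- run_block(net, schedule$decay_epochs, decay = TRUE)
    net <- delete_small_weights(net, schedule$weight_delete_threshold)
    reset_state(net)
    net <- run_block(net, schedule$retrain_epochs, decay = FALSE)
  }
  partial <- net

  net <- delete_inactive_units(net, task, seed = probe_seeds[1],
                               activity_window = schedule$activity_window,
                               activity_floor = schedule$activity_floor)
  reset_state(net)
  net <- run_block(net, schedule$unit_retrain_epochs, decay = FALSE)
  net <- run_block(net, schedule$unit_decay_epochs, decay = TRUE)
  net <- delete_small_weights(net, schedule$weight_delete_threshold)
  reset_state(net)

  for (r in seq_len(schedule$extra_unit_rounds)) {
    net <- delete_inactive_units(net, task, seed = probe_seeds[r + 1L],
                                 activity_window = schedule$activity_window,
                                 activity_floor = schedule$activity_floor)
    reset_state(net)
    net <- run_block(net, schedule$extra_retrain_epochs, decay = FALSE)
  }
  stopifnot(epoch == unname(cps["reduced"]))
  # final history row reflects the fully reduced network
  history <- rbind(history,
                   data.frame(epoch = epoch, hidden_units = count_live_units(net),
                              weights = count_weights(net),
                              percent_error = percent_error_on(net, test)))
  history <- history[!duplicated(history$epoch, fromLast = TRUE), ]
  history <- history[order(history$epoch), ]
  rownames(history) <- NULL
  list(checkpoints = list(unreduced = unreduced, partial = partial,
                          reduced = net),
       network = net, history = history)
}
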