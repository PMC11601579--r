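#' Configure training
#'
#' Training descends the mean-squared output error by backpropagation
#' through time. Each epoch draws fresh episodes and line-searches two
#' candidate directions: the normalized steepest-descent direction and a
#' second-order estimate that rescales each weight's gradient by running
#' moment estimates of its history (so weights feeding silent, offset-
#' suppressed units keep moving despite their tiny derivatives). The
#' candidate that strictly lowers the error on that epoch's episodes wins;
#' weights are then projected back into their sign-class bounds and, when
#' decay is active, all magnitudes shrink toward zero.
#'
#' @param episodes_per_epoch episodes drawn per training epoch (default 1).
#' @param epoch_length steps per episode (default 20).
#' @param weight_decay_amount magnitude removed from every weight per epoch
#'   when decay is active (default 0.001).
#' @param line_search_max_evals maximum error evaluations per search
#'   direction (default 12).
#' @param line_search_initial_step starting step length; adapted across
#'   epochs (doubled while improving, halved after a failed search).
#' @param flat_spot optional constant added to the logistic derivative when
#'   forming the training search direction (default 0, i.e. the exact
#'   gradient; nonzero values implement classic flat-spot elimination).
#' @param eval_every record test-set error every this many epochs
#'   (default 500).
#' @param n_test_episodes size of the held-out test stream used for the
#'   recorded error (default 100).
#' @param seed optional root seed.
#' @return an object of class \code{sah_training_config}.
#' @export
training_config <- function(episodes_per_epoch = 1L, epoch_length = 20L,
                            weight_decay_amount = 0.001,
                            line_search_max_evals = 12L,
                            line_search_initial_step = 0.5,
                            flat_spot = 0,
                            eval_every = 500L, n_test_episodes = 100L,
                            seed = NULL) {
  if (weight_decay_amount < 0) stop("decay amount must be >= 0", call. = FALSE)
  if (episodes_per_epoch < 1) stop("need >= 1 episode per epoch", call. = FALSE)
  structure(list(episodes_per_epoch = as.integer(episodes_per_epoch),
                 epoch_length = as.integer(epoch_length),
                 weight_decay_amount = weight_decay_amount,
                 line_search_max_evals = as.integer(line_search_max_evals),
                 line_search_initial_step = line_search_initial_step,
                 flat_spot = flat_spot,
                 eval_every = as.integer(eval_every),
                 n_test_episodes = as.integer(n_test_episodes),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sah_training_config")
}

#' Root-mean-square output error
#'
#' The error reported throughout is the square root of the mean squared
#' difference between outputs and targets over all valid (step, output)
#' cells, as a fraction in \[0, 1\]; multiply by 100 for percent.
#'
#' @param outputs matrix (steps x outputs) of network outputs.
#' @param targets matrix of the same shape.
#' @param valid_mask logical vector marking steps with defined targets
#'   (default: all steps with non-NA targets).
#' @return the RMS error.
#' @export
rms_error <- function(outputs, targets, valid_mask = NULL) {
  outputs <- as.matrix(outputs)
  targets <- as.matrix(targets)
  if (!all(dim(outputs) == dim(targets)))
    stop("`outputs` and `targets` must have the same shape", call. = FALSE)
  if (is.null(valid_mask)) valid_mask <- !apply(is.na(targets), 1, any)
  if (!any(valid_mask)) stop("no valid steps: the error is undefined", call. = FALSE)
  d <- outputs[valid_mask, , drop = FALSE] - targets[valid_mask, , drop = FALSE]
  sqrt(mean(d^2))
}

#' Exact BPTT gradient of the mean-squared-error objective
#'
#' Backpropagates through the unrolled one-step-delay dynamics of one or
#' more episodes and returns the gradient of the MSE (averaged over
#' episodes) with respect to every present weight. Entries for masked-out
#' connections are zero.
#'
#' @param network an \code{sah_network}.
#' @param episodes an \code{sah_episode} or a list of them.
#' @return a list with \code{gradient} (units x units matrix) and
#'   \code{mse} (the objective value).
#' @export
compute_gradient <- function(network, episodes) {
  if (inherits(episodes, "sah_episode")) episodes <- list(episodes)
  N <- length(network$alive)
  G <- matrix(0, N, N, dimnames = dimnames(network$weights))
  mse <- 0
  used <- 0L
  for (ep in episodes) {
    if (nrow(ep$inputs) == 0L) next
    tg <- ep$targets
    tg[is.na(tg)] <- 0
    r <- cpp_grad(network$weights, network$mask, ep$inputs, tg, ep$valid,
                  network$alive, network$spec$offset, network$spec$temperature)
    G <- G + r$gradient
    mse <- mse + r$mse
    used <- used + 1L
  }
  if (used == 0L) return(list(gradient = G, mse = NA_real_))
  list(gradient = G / used, mse = mse / used)
}

#' Shrink all weight magnitudes toward zero
#'
#' Applies one step of weight decay: \code{|w| <- max(0, |w| - amount)}
#' preserving sign. Magnitudes may fall below the sign-class minimum; such
#' weights become candidates for deletion.
#'
#' @param network an \code{sah_network}.
#' @param amount non-negative decay amount.
#' @return the decayed network.
#' @export
apply_weight_decay <- function(network, amount) {
  if (amount < 0) stop("`amount` must be >= 0", call. = FALSE)
  W <- network$weights
  m <- pmax(abs(W) - amount, 0)
  W2 <- sign(W) * m
  W2[!network$mask] <- 0
  network$weights <- W2
  network
}

# Fresh optimizer state for the C++ phase runner.
new_opt_state <- function(network, config) {
  N <- length(network$alive)
  list(have_prev = FALSE, m1 = matrix(0, N, N), m2 = matrix(0, N, N),
       t_moments = 0,
       step1 = config$line_search_initial_step,
       step2 = config$line_search_initial_step)
}

# Run one training phase through the C++ loop. `test` is the fixed
# evaluation stream from episodes_to_arrays(); decay_amount 0 disables decay.
train_phase <- function(network, task, n_epochs, config, decay_amount, state,
                        test, seed, epoch_offset = 0L) {
  if (n_epochs == 0L)
    return(list(network = network, state = state,
                history = data.frame(epoch = integer(0), percent_error = numeric(0))))
  arrs <- episodes_to_arrays(task, n_epochs * config$episodes_per_epoch, seed)
  b <- bounds_matrices(network)
  res <- cpp_train_phase(network$weights, network$mask, b$lb, b$ub,
                         network$alive, arrs$inputs, arrs$targets, arrs$n,
                         arrs$T, arrs$n_in, arrs$n_out, arrs$valid,
                         network$spec$offset, network$spec$temperature,
                         n_epochs, config$episodes_per_epoch, decay_amount,
                         state, config$line_search_max_evals,
                         config$flat_spot,
                         test$inputs, test$targets, test$n,
                         config$eval_every, as.integer(epoch_offset))
  W <- res$weights
  dimnames(W) <- dimnames(network$weights)
  network$weights <- W
  list(network = network, state = res$state,
       history = data.frame(epoch = res$history_epoch,
                            percent_error = res$history_error))
}

# Percent error of a network on a pre-built test array set.
percent_error_on <- function(network, test) {
  cpp_test_error(network$weights, test$inputs, test$targets, test$n, test$T,
                 test$n_in, test$n_out, test$valid, network$alive,
                 network$spec$offset, network$spec$temperature)
}

#' Train a network by gradient descent with line search
#'
#' Runs \code{n_epochs} of training on freshly generated episodes of the
#' task. Accepted steps never increase the objective on the training
#' episodes (a failed line search leaves the weights unchanged for that
#' epoch). Test error is measured on an independent, fixed 100-episode
#' stream at a regular cadence.
#'
#' @param network an \code{sah_network}.
#' @param task a \code{\link{task_config}}.
#' @param n_epochs number of training epochs.
#' @param config a \code{\link{training_config}}.
#' @param decay apply weight decay after every epoch?
#' @param seed root seed controlling the training and test streams.
#' @param state optional optimizer state from a previous call, to continue
#'   a run seamlessly.
#' @param epoch_offset value added to epoch indices in the history.
#' @return a list with the trained \code{network}, a \code{history} data
#'   frame (epoch, hidden_units, weights, percent_error) and the optimizer
#'   \code{state}.
#' @export
train <- function(network, task, n_epochs, config = training_config(),
                  decay = FALSE, seed = NULL, state = NULL,
                  epoch_offset = 0L) {
  stopifnot(inherits(network, "sah_network"), inherits(task, "sah_task_config"))
  seeds <- derive_seeds(if (is.null(seed)) config$seed else seed, 2L)
  test <- episodes_to_arrays(task, config$n_test_episodes, seeds[2])
  if (is.null(state)) state <- new_opt_state(network, config)
  res <- train_phase(network, task, as.integer(n_epochs), config,
                     if (decay) config$weight_decay_amount else 0,
                     state, test, seeds[1], epoch_offset)
  h <- res$history
  if (nrow(h)) {
    h$hidden_units <- count_live_units(res$network)
    h$weights <- count_weights(res$network)
    h <- h[, c("epoch", "hidden_units", "weights", "percent_error")]
  } else {
    h <- data.frame(epoch = integer(0), hidden_units = integer(0),
                    weights = integer(0), percent_error = numeric(0))
  }
  list(network = res$network, history = h, state = res$state)
}
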