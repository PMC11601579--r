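#' Configure the sample-and-hold task
#'
#' Defines a sample-and-hold (SAH) short-term memory task on one or two
#' continuous input signals. With two signals each is built as
#' \code{Signal_k = alpha * C + U_k(0, 1 - alpha)} where \code{C ~ U(0, alpha)}
#' is a shared common-mode value redrawn every time-step, so \code{alpha = 0}
#' gives independent signals and \code{alpha = 1} identical ones. A binary
#' gate pulse marks sampling times; the target outputs are the gated samples
#' delayed by \code{target_delay} steps to accommodate network propagation.
#'
#' @param alpha common-mode fraction in \[0, 1\].
#' @param epoch_length number of time-steps per episode (default 20).
#' @param gate_spacing_min,gate_spacing_max inclusive bounds on the number of
#'   steps between successive gate pulses (defaults 3 and 6).
#' @param target_delay delay, in steps, between a held sample and its
#'   appearance as a target (default 2, matching the two-step propagation
#'   delay from input to output units).
#' @param n_signals 1 or 2; 1 gives the classic single-input SAH task.
#' @param seed optional integer seed recorded in the config and used by
#'   generators when no explicit seed is passed.
#' @return an object of class \code{sah_task_config}.
#' @export
task_config <- function(alpha = 0, epoch_length = 20L, gate_spacing_min = 3L,
                        gate_spacing_max = 6L, target_delay = 2L,
                        n_signals = 2L, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("`alpha` must be a single value in [0, 1]", call. = FALSE)
  epoch_length <- as.integer(epoch_length)
  gate_spacing_min <- as.integer(gate_spacing_min)
  gate_spacing_max <- as.integer(gate_spacing_max)
  target_delay <- as.integer(target_delay)
  n_signals <- as.integer(n_signals)
  if (epoch_length < 0) stop("`epoch_length` must be >= 0", call. = FALSE)
  if (gate_spacing_min < 1 || gate_spacing_max < gate_spacing_min)
    stop("need 1 <= gate_spacing_min <= gate_spacing_max", call. = FALSE)
  if (epoch_length > 0 && target_delay >= epoch_length)
    stop("`target_delay` must be smaller than `epoch_length`", call. = FALSE)
  if (target_delay < 0) stop("`target_delay` must be >= 0", call. = FALSE)
  if (!n_signals %in% c(1L, 2L)) stop("`n_signals` must be 1 or 2", call. = FALSE)
  structure(list(alpha = alpha, epoch_length = epoch_length,
                 gate_spacing_min = gate_spacing_min,
                 gate_spacing_max = gate_spacing_max,
                 target_delay = target_delay, n_signals = n_signals,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sah_task_config")
}

#' @export
print.sah_task_config <- function(x, ...) {
  cat(sprintf(
    "SAH task: alpha = %g, %d signal(s), %d steps/episode, gates every %d-%d steps, target delay %d\n",
    x$alpha, x$n_signals, x$epoch_length, x$gate_spacing_min,
    x$gate_spacing_max, x$target_delay))
  invisible(x)
}

# Input column names for a task config (Gate, Signal..., Bias).
task_input_names <- function(config) {
  c("Gate", paste0("Signal", seq_len(config$n_signals)), "Bias")
}

#' Generate one task episode
#'
#' Draws a fresh episode of the sample-and-hold task. Each step draws a
#' common-mode value \code{C ~ U(0, alpha)} and independent
#' \code{U_k ~ U(0, 1 - alpha)}, giving \code{Signal_k = alpha * C + U_k}.
#' A gate pulse occurs at step 1 (so held samples are defined from the start
#' of the episode) and thereafter at intervals drawn uniformly from
#' \code{gate_spacing_min:gate_spacing_max}. Held samples update at gate
#' steps; targets are the held samples delayed by \code{target_delay} steps,
#' and the validity mask is \code{FALSE} for the initial steps where no
#' target exists yet.
#'
#' @param config a \code{\link{task_config}}.
#' @param seed optional integer seed; falls back to \code{config$seed}; if
#'   both are \code{NULL} the current RNG stream is used.
#' @return an object of class \code{sah_episode} with elements
#'   \code{inputs} (epoch_length x n_inputs matrix with columns Gate,
#'   Signal1\[, Signal2\], Bias), \code{targets} (epoch_length x n_signals,
#'   \code{NA} where undefined), \code{samples} (the held samples),
#'   \code{valid} (logical), and \code{config}.
#' @export
generate_episode <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sah_task_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  if (!is.null(seed)) set.seed(seed)
  T <- config$epoch_length
  ns <- config$n_signals
  nms <- task_input_names(config)
  if (T == 0L) {
    return(structure(list(
      inputs = matrix(numeric(0), 0, ns + 2L, dimnames = list(NULL, nms)),
      targets = matrix(numeric(0), 0, ns),
      samples = matrix(numeric(0), 0, ns),
      valid = logical(0), config = config), class = "sah_episode"))
  }
  a <- config$alpha
  gate <- integer(T)
  pos <- 1L
  gate[1L] <- 1L
  repeat {
    pos <- pos + sample(config$gate_spacing_min:config$gate_spacing_max, 1L)
    if (pos > T) break
    gate[pos] <- 1L
  }
  C <- stats::runif(T, 0, a)
  sig <- matrix(0, T, ns)
  for (k in seq_len(ns)) sig[, k] <- a * C + stats::runif(T, 0, 1 - a)
  gidx <- which(gate == 1L)
  hold <- findInterval(seq_len(T), gidx)
  samples <- sig[gidx, , drop = FALSE][hold, , drop = FALSE]
  d <- config$target_delay
  targets <- matrix(NA_real_, T, ns)
  if (d < T) targets[(d + 1L):T, ] <- samples[seq_len(T - d), , drop = FALSE]
  valid <- !is.na(targets[, 1L])
  inputs <- cbind(gate, sig, rep(1, T))
  colnames(inputs) <- nms
  structure(list(inputs = inputs, targets = targets, samples = samples,
                 valid = valid, config = config),
            class = "sah_episode")
}

#' Generate a reproducible stream of episodes
#'
#' Expands one root seed into independent per-episode seeds so that training
#' and test streams can be generated reproducibly and without overlap.
#'
#' @param config a \code{\link{task_config}}.
#' @param n number of episodes.
#' @param seed integer root seed (optional).
#' @return a list of \code{sah_episode} objects.
#' @export
generate_episodes <- function(config, n, seed = NULL) {
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i) generate_episode(config, seed = seeds[i]))
}

# Derive n child seeds (< 2^31) from one root seed; NULL root draws from the
# current stream.
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Stack episodes into the flat arrays the C++ training loop consumes.
episodes_to_arrays <- function(config, n, seed = NULL) {
  seeds <- derive_seeds(seed, n)
  T <- config$epoch_length
  ns <- config$n_signals
  n_in <- ns + 2L
  inputs <- numeric(T * n_in * n)
  targets <- numeric(T * ns * n)
  valid <- NULL
  for (i in seq_len(n)) {
    ep <- generate_episode(config, seed = seeds[i])
    inputs[((i - 1L) * T * n_in + 1L):(i * T * n_in)] <- ep$inputs
    tg <- ep$targets
    tg[is.na(tg)] <- 0
    targets[((i - 1L) * T * ns + 1L):(i * T * ns)] <- tg
    if (is.null(valid)) valid <- ep$valid
  }
  list(inputs = inputs, targets = targets, valid = valid, n = n, T = T,
       n_in = n_in, n_out = ns)
}

#' Correlation between the two generated signals
#'
#' Diagnostic for the degree of signal commonality: Pearson correlation of
#' Signal1 and Signal2 over a long generated sequence.
#'
#' @param alpha common-mode fraction in \[0, 1\].
#' @param n_steps number of time-steps to simulate (>= 100).
#' @param seed optional integer seed.
#' @return the sample correlation coefficient.
#' @export
signal_correlation <- function(alpha, n_steps = 10000L, seed = NULL) {
  if (n_steps < 100) stop("`n_steps` must be >= 100", call. = FALSE)
  cfg <- task_config(alpha = alpha, epoch_length = as.integer(n_steps),
                     n_signals = 2L)
  ep <- generate_episode(cfg, seed = seed)
  s1 <- ep$inputs[, "Signal1"]
  s2 <- ep$inputs[, "Signal2"]
  stats::cor(s1, s2)
}

#' @export
print.sah_episode <- function(x, ...) {
  cat(sprintf("SAH episode: %d steps, %d signal(s), alpha = %g, %d gate pulses\n",
              nrow(x$inputs), x$config$n_signals, x$config$alpha,
              sum(x$inputs[, "Gate"])))
  invisible(x)
}

#' @export
as.data.frame.sah_episode <- function(x, ...) {
  ns <- x$config$n_signals
  d <- data.frame(step = seq_len(nrow(x$inputs)),
                  gate = x$inputs[, "Gate"])
  for (k in seq_len(ns)) d[[paste0("signal", k)]] <- x$inputs[, paste0("Signal", k)]
  d$bias <- x$inputs[, "Bias"]
  for (k in seq_len(ns)) d[[paste0("target", k)]] <- x$targets[, k]
  d$valid <- x$valid
  d
}

#' Write an episode to CSV
#'
#' One row per time-step with columns step, gate, signal(s), bias,
#' target(s) and valid.
#'
#' @param episode an \code{sah_episode}.
#' @param path output file path.
#' @export
write_episode_csv <- function(episode, path) {
  utils::write.csv(as.data.frame(episode), path, row.names = FALSE)
  invisible(path)
}
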