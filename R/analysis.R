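#' Measure a network's percent error on fresh task episodes
#'
#' Generates \code{n_epochs} independent episodes, simulates each, and
#' returns the mean over episodes of the RMS output error (valid steps
#' only) times 100.
#'
#' @param network an \code{sah_network}.
#' @param task a \code{\link{task_config}}.
#' @param n_epochs number of test episodes (default 100).
#' @param seed optional seed for the test stream.
#' @param per_output if TRUE, also return each output unit's own percent
#'   error.
#' @return the mean percent error, or (with \code{per_output}) a list with
#'   \code{overall} and \code{per_output}.
#' @export
evaluate_network <- function(network, task, n_epochs = 100L, seed = NULL,
                             per_output = FALSE) {
  stopifnot(inherits(network, "sah_network"), inherits(task, "sah_task_config"))
  seeds <- derive_seeds(seed, n_epochs)
  n_out <- network$spec$n_outputs
  oidx <- output_idx(network)
  tot <- 0
  tot_k <- numeric(n_out)
  for (i in seq_len(n_epochs)) {
    ep <- generate_episode(task, seed = seeds[i])
    trace <- run_episode(network, ep)
    out <- trace[, oidx, drop = FALSE]
    tot <- tot + rms_error(out, ep$targets, ep$valid)
    if (per_output)
      for (k in seq_len(n_out))
        tot_k[k] <- tot_k[k] + rms_error(out[, k, drop = FALSE],
                                         ep$targets[, k, drop = FALSE],
                                         ep$valid)
  }
  overall <- 100 * tot / n_epochs
  if (!per_output) return(overall)
  list(overall = overall,
       per_output = stats::setNames(100 * tot_k / n_epochs,
                                    network$unit_names[oidx]))
}

#' Cross-common-mode error matrix
#'
#' Evaluates each trained network on test streams spanning the common-mode
#' grid. All networks see matched test streams at each tested level, so
#' rows are directly comparable.
#'
#' @param networks a named list of \code{sah_network}s; names are the
#'   trained common-mode fractions (e.g. \code{"0"}, \code{"0.1"}, ...).
#' @param task_template a \code{\link{task_config}} supplying everything
#'   but \code{alpha}.
#' @param tested_alphas grid of tested common-mode fractions
#'   (default \code{seq(0, 1, 0.1)}).
#' @param n_test_epochs test episodes per cell (default 100).
#' @param seed root seed; each tested level gets its own derived stream.
#' @return an object of class \code{sah_cross_cm} containing the
#'   (trained x tested) mean percent error matrix.
#' @export
cross_cm_matrix <- function(networks, task_template = task_config(),
                            tested_alphas = seq(0, 1, 0.1),
                            n_test_epochs = 100L, seed = NULL) {
  if (is.null(names(networks)) || any(!nzchar(names(networks))))
    stop("`networks` must be a list named by trained alpha", call. = FALSE)
  trained <- as.numeric(names(networks))
  if (any(is.na(trained)))
    stop("`networks` names must parse as numeric alphas", call. = FALSE)
  bad <- vapply(networks, function(n) !inherits(n, "sah_network"), logical(1))
  if (any(bad))
    stop("missing or invalid network for trained alpha ",
         paste(names(networks)[bad], collapse = ", "), call. = FALSE)
  col_seeds <- derive_seeds(seed, length(tested_alphas))
  M <- matrix(NA_real_, length(trained), length(tested_alphas),
              dimnames = list(trained = format(trained),
                              tested = format(tested_alphas)))
  for (j in seq_along(tested_alphas)) {
    tcfg <- task_config(alpha = tested_alphas[j],
                        epoch_length = task_template$epoch_length,
                        gate_spacing_min = task_template$gate_spacing_min,
                        gate_spacing_max = task_template$gate_spacing_max,
                        target_delay = task_template$target_delay,
                        n_signals = task_template$n_signals)
    for (i in seq_along(trained))
      M[i, j] <- evaluate_network(networks[[i]], tcfg, n_test_epochs,
                                  seed = col_seeds[j])
  }
  structure(list(trained_alphas = trained, tested_alphas = tested_alphas,
                 mean_percent_error = M, n_test_epochs = n_test_epochs),
            class = "sah_cross_cm")
}

#' @export
print.sah_cross_cm <- function(x, ...) {
  cat("Cross-common-mode mean percent error (trained x tested):\n")
  print(round(x$mean_percent_error, 2))
  invisible(x)
}

#' @export
as.data.frame.sah_cross_cm <- function(x, ...) {
  g <- expand.grid(trained_alpha = x$trained_alphas,
                   tested_alpha = x$tested_alphas)
  g$percent_error <- as.vector(x$mean_percent_error)
  g
}

#' Remove all outgoing weights of named inputs
#'
#' Returns a lesioned copy of the network in which every connection leaving
#' the named input units has been removed, for measuring how strongly each
#' output depends on each input.
#'
#' @param network an \code{sah_network}.
#' @param input_names character vector of input unit names
#'   (e.g. \code{"Signal2"}).
#' @return the lesioned network.
#' @export
lesion_inputs <- function(network, input_names) {
  idx <- match(input_names, network$unit_names)
  if (any(is.na(idx)))
    stop("unknown input unit(s): ",
         paste(input_names[is.na(idx)], collapse = ", "), call. = FALSE)
  roles <- network$unit_roles[idx]
  if (any(!roles %in% c("task-input", "bias")))
    stop("can only lesion input or bias units", call. = FALSE)
  network$mask[, idx] <- FALSE
  network$weights[, idx] <- 0
  network
}

#' Per-output error change under an input lesion
#'
#' Evaluates each output's percent error before and after removing all
#' weights from the named inputs, on matched test streams. The increase
#' column is the decoupling index: a small value means the output barely
#' depends on the lesioned input.
#'
#' @param network an \code{sah_network}.
#' @param task a \code{\link{task_config}}.
#' @param input_names inputs to lesion.
#' @param n_epochs test episodes (default 100).
#' @param seed optional seed (shared by both evaluations).
#' @return a data frame with columns output, before, after, increase
#'   (percent points).
#' @export
lesion_report <- function(network, task, input_names, n_epochs = 100L,
                          seed = NULL) {
  if (is.null(seed)) seed <- derive_seeds(NULL, 1L)
  before <- evaluate_network(network, task, n_epochs, seed, per_output = TRUE)
  les <- lesion_inputs(network, input_names)
  after <- evaluate_network(les, task, n_epochs, seed, per_output = TRUE)
  data.frame(output = names(before$per_output),
             before = unname(before$per_output),
             after = unname(after$per_output),
             increase = unname(after$per_output - before$per_output))
}

#' Map fixed-point attractors over a grid of held samples
#'
#' For every pair of sample values on an 11x11 grid the network receives a
#' single pulse step (Gate = 1, the two signal values, Bias = 1) followed
#' by \code{relaxation_steps} steps with the task inputs at zero, and the
#' output activities at the final step are recorded as the attractor
#' values. By default the constant bias input stays at 1 during the
#' relaxation, matching normal operating conditions; without it the
#' offset-4 logistic units lose their operating point and every map
#' collapses to a single silent attractor. Set
#' \code{bias_during_relaxation = FALSE} for a fully autonomous
#' relaxation.
#'
#' @param network a dual-input \code{sah_network}.
#' @param relaxation_steps steps of silence after the pulse (default 100).
#' @param grid sample values (default \code{seq(0, 1, 0.1)}).
#' @param bias_during_relaxation keep the bias input at 1 during the
#'   relaxation?
#' @return an object of class \code{sah_attractor_map} with per-output
#'   value matrices over the grid.
#' @export
attractor_map <- function(network, relaxation_steps = 100L,
                          grid = seq(0, 1, 0.1),
                          bias_during_relaxation = TRUE) {
  ni <- n_inputs(network)
  if (ni != 4L)
    stop("`attractor_map` expects a dual-input network (Gate, Signal1, Signal2, Bias)",
         call. = FALSE)
  oidx <- output_idx(network)
  n_out <- length(oidx)
  vals <- array(NA_real_, c(length(grid), length(grid), n_out),
                dimnames = list(sample1 = format(grid),
                                sample2 = format(grid),
                                output = network$unit_names[oidx]))
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      inputs <- matrix(0, 1L + relaxation_steps, ni)
      inputs[1L, ] <- c(1, grid[i], grid[j], 1)
      if (bias_during_relaxation) inputs[, ni] <- 1
      trace <- run_episode(network, inputs)
      vals[i, j, ] <- trace[nrow(trace), oidx]
    }
  }
  structure(list(grid = grid, values = vals,
                 relaxation_steps = as.integer(relaxation_steps),
                 bias_during_relaxation = bias_during_relaxation),
            class = "sah_attractor_map")
}

#' @export
print.sah_attractor_map <- function(x, ...) {
  cat(sprintf("Attractor map: %dx%d sample grid, %d relaxation steps, %d output(s)\n",
              length(x$grid), length(x$grid), x$relaxation_steps,
              dim(x$values)[3]))
  invisible(x)
}

#' @export
as.data.frame.sah_attractor_map <- function(x, ...) {
  g <- expand.grid(sample1 = x$grid, sample2 = x$grid)
  for (k in seq_len(dim(x$values)[3]))
    g[[paste0("output", k)]] <- as.vector(x$values[, , k])
  g
}

#' Correlation between the two outputs' attractor values
#'
#' Over the whole sample grid; rises as networks trained at higher
#' common mode make the two outputs interdependent.
#'
#' @param map an \code{sah_attractor_map} with two outputs.
#' @export
attractor_interdependence <- function(map) {
  stopifnot(dim(map$values)[3] >= 2)
  stats::cor(as.vector(map$values[, , 1]), as.vector(map$values[, , 2]))
}

#' Trace the relaxation to a fixed point
#'
#' Presents a single pulse (Gate plus the given sample values) and then
#' silence, returning the full activity trace so the approach to the
#' attractor can be inspected, e.g. across activation temperatures.
#' With \code{n_steps = 0} the initial (all-zero) state is returned.
#'
#' @param network an \code{sah_network}.
#' @param sample1 sample value for Signal1.
#' @param sample2 sample value for Signal2 (omit for single-input
#'   networks).
#' @param n_steps relaxation steps after the pulse (default 100).
#' @param bias_during_relaxation keep the bias at 1 during relaxation
#'   (default TRUE, as in \code{\link{attractor_map}})?
#' @return a (time x units) activity matrix; the first row is the pulse
#'   step.
#' @export
relaxation_trace <- function(network, sample1, sample2 = NULL,
                             n_steps = 100L,
                             bias_during_relaxation = TRUE) {
  ni <- n_inputs(network)
  N <- length(network$alive)
  if (n_steps == 0L) {
    out <- matrix(0, 1, N, dimnames = list(NULL, network$unit_names))
    return(out)
  }
  pulse <- if (ni == 4L) c(1, sample1, sample2, 1)
           else if (ni == 3L) c(1, sample1, 1)
           else stop("unsupported input layout", call. = FALSE)
  inputs <- matrix(0, 1L + n_steps, ni)
  inputs[1L, ] <- pulse
  if (bias_during_relaxation) inputs[, ni] <- 1
  run_episode(network, inputs)
}

#' Count distinct terminal attractor values
#'
#' Runs \code{\link{relaxation_trace}} from a range of initial sample
#' values and counts the clusters of terminal output values, merging
#' values closer than \code{tol}.
#'
#' @param network an \code{sah_network}.
#' @param samples initial sample values (default \code{seq(0, 1, 0.1)});
#'   for dual-input networks the same value is used for both signals.
#' @param n_steps relaxation length (default 100).
#' @param tol cluster merge tolerance (default 1e-3).
#' @return the number of distinct terminal values of the first output.
#' @export
count_attractors <- function(network, samples = seq(0, 1, 0.1),
                             n_steps = 100L, tol = 1e-3) {
  ni <- n_inputs(network)
  oidx <- output_idx(network)[1]
  terminal <- vapply(samples, function(s) {
    tr <- if (ni == 4L) relaxation_trace(network, s, s, n_steps)
          else relaxation_trace(network, s, n_steps = n_steps)
    tr[nrow(tr), oidx]
  }, numeric(1))
  v <- sort(terminal)
  1L + sum(diff(v) > tol)
}

#' Classify a trained network's solution strategy
#'
#' Dual-input networks fall into three regimes: processing the two signals
#' through essentially independent sub-networks (\code{"decoupled"}),
#' splitting them into common and differential components
#' (\code{"common-differential"}), or collapsing onto a single averaged
#' signal (\code{"averaging"}). Classification uses output agreement (the
#' correlation of the two output traces on fresh episodes) and the
#' cross-lesion decoupling indices (error increase of each output when the
#' opposite signal input is lesioned).
#'
#' @param network a dual-input \code{sah_network}.
#' @param task the task it was trained on.
#' @param n_epochs test episodes (default 100).
#' @param seed optional seed.
#' @param decoupling_threshold maximum cross-lesion error increase, in
#'   percent points, for a decoupled verdict (default 2).
#' @param averaging_correlation minimum output-trace correlation for an
#'   averaging verdict (default 0.95).
#' @return a character scalar (one of \code{"decoupled"},
#'   \code{"common-differential"}, \code{"averaging"}) with the measured
#'   indices attached as attribute \code{"details"}.
#' @export
solution_type <- function(network, task, n_epochs = 100L, seed = NULL,
                          decoupling_threshold = 2,
                          averaging_correlation = 0.95) {
  if (task$n_signals != 2L)
    stop("`solution_type` requires the dual-signal task", call. = FALSE)
  if (is.null(seed)) seed <- derive_seeds(NULL, 1L)
  seeds <- derive_seeds(seed, n_epochs)
  oidx <- output_idx(network)
  o1 <- o2 <- numeric(0)
  for (i in seq_len(n_epochs)) {
    ep <- generate_episode(task, seed = seeds[i])
    tr <- run_episode(network, ep)
    o1 <- c(o1, tr[ep$valid, oidx[1]])
    o2 <- c(o2, tr[ep$valid, oidx[2]])
  }
  agreement <- stats::cor(o1, o2)
  r2 <- lesion_report(network, task, "Signal2", n_epochs, seed)
  r1 <- lesion_report(network, task, "Signal1", n_epochs, seed)
  d12 <- r2$increase[1]  # Output1 error rise when Signal2 is removed
  d21 <- r1$increase[2]  # Output2 error rise when Signal1 is removed
  type <- if (!is.na(agreement) && agreement > averaging_correlation) {
    "averaging"
  } else if (d12 < decoupling_threshold && d21 < decoupling_threshold) {
    "decoupled"
  } else {
    "common-differential"
  }
  attr(type, "details") <- list(output_agreement = agreement,
                                cross_lesion = c(output1_vs_signal2 = d12,
                                                 output2_vs_signal1 = d21))
  type
}
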