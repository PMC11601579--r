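#' Specify a sign-constrained recurrent network
#'
#' Units are arranged as task inputs, a constant bias input, excitatory
#' hidden units, inhibitory hidden units, and output units. Connectivity
#' follows Dale's principle: every weight leaving an excitatory unit is
#' positive, every weight leaving an inhibitory unit negative, and weights
#' from input and bias units are unsigned. Task inputs project to hidden
#' units only; the bias also projects to outputs; hidden units project to
#' hidden and output units with no self-connections and no
#' inhibitory-to-inhibitory links; outputs project nowhere.
#'
#' @param n_task_inputs number of task input units (3 for the dual task:
#'   Gate, Signal1, Signal2; 2 for the single-input task).
#' @param n_excitatory,n_inhibitory hidden unit counts (defaults 16 and 16).
#' @param n_outputs number of output units (default 2).
#' @param offset activation offset applied to every non-input unit's summed
#'   input (default 4), keeping units nearly silent without positive drive.
#' @param temperature inverse-slope of the logistic activation; the unit
#'   activation is \code{1 / (1 + exp(-(net - offset) / temperature))}.
#' @param bounds named list of \code{c(lower, upper)} weight bounds per sign
#'   class (\code{input}, \code{excitatory}, \code{inhibitory}).
#' @param has_bias include the constant bias input (default TRUE).
#' @return an object of class \code{sah_network_spec}.
#' @export
network_spec <- function(n_task_inputs = 3L, n_excitatory = 16L,
                         n_inhibitory = 16L, n_outputs = 2L, offset = 4,
                         temperature = 1,
                         bounds = list(input = c(-8, 8),
                                       excitatory = c(0.001, 8),
                                       inhibitory = c(-8, -0.001)),
                         has_bias = TRUE) {
  n_task_inputs <- as.integer(n_task_inputs)
  n_excitatory <- as.integer(n_excitatory)
  n_inhibitory <- as.integer(n_inhibitory)
  n_outputs <- as.integer(n_outputs)
  if (any(c(n_task_inputs, n_excitatory, n_inhibitory, n_outputs) < 0))
    stop("unit counts must be >= 0", call. = FALSE)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("`temperature` must be > 0", call. = FALSE)
  stopifnot(all(c("input", "excitatory", "inhibitory") %in% names(bounds)))
  structure(list(n_task_inputs = n_task_inputs, has_bias = isTRUE(has_bias),
                 n_excitatory = n_excitatory, n_inhibitory = n_inhibitory,
                 n_outputs = n_outputs, offset = offset,
                 temperature = temperature, bounds = bounds),
            class = "sah_network_spec")
}

# Unit roles in canonical order.
spec_roles <- function(spec) {
  c(rep("task-input", spec$n_task_inputs),
    if (spec$has_bias) "bias",
    rep("excitatory-hidden", spec$n_excitatory),
    rep("inhibitory-hidden", spec$n_inhibitory),
    rep("output", spec$n_outputs))
}

spec_unit_names <- function(spec) {
  task <- if (spec$n_task_inputs == 3L) c("Gate", "Signal1", "Signal2")
          else if (spec$n_task_inputs == 2L) c("Gate", "Signal1")
          else paste0("Input", seq_len(spec$n_task_inputs))
  c(task, if (spec$has_bias) "Bias",
    if (spec$n_excitatory) paste0("e", seq_len(spec$n_excitatory)),
    if (spec$n_inhibitory) paste0("i", seq_len(spec$n_inhibitory)),
    if (spec$n_outputs) paste0("Output", seq_len(spec$n_outputs)))
}

# Allowed-connection mask (to-unit x from-unit) implied by the spec.
build_mask <- function(spec) {
  roles <- spec_roles(spec)
  N <- length(roles)
  task <- which(roles == "task-input")
  bias <- which(roles == "bias")
  exc <- which(roles == "excitatory-hidden")
  inh <- which(roles == "inhibitory-hidden")
  out <- which(roles == "output")
  hid <- c(exc, inh)
  mask <- matrix(FALSE, N, N)
  mask[hid, c(task, bias)] <- TRUE   # inputs drive hidden units
  mask[out, bias] <- TRUE            # bias also drives outputs
  mask[c(hid, out), exc] <- TRUE     # excitatory -> hidden + outputs
  mask[c(exc, out), inh] <- TRUE     # inhibitory -> excitatory + outputs
  diag(mask) <- FALSE                # no self-connections
  dimnames(mask) <- list(spec_unit_names(spec), spec_unit_names(spec))
  mask
}

# Sign class of each from-unit column: "input", "excitatory", "inhibitory"
# or NA for outputs (which project nowhere).
column_classes <- function(spec) {
  roles <- spec_roles(spec)
  ifelse(roles %in% c("task-input", "bias"), "input",
         ifelse(roles == "excitatory-hidden", "excitatory",
                ifelse(roles == "inhibitory-hidden", "inhibitory", NA)))
}

# Per-entry lower/upper bound matrices; masked-out entries are pinned to 0.
bounds_matrices <- function(network) {
  spec <- network$spec
  cls <- column_classes(spec)
  N <- length(cls)
  lb <- matrix(0, N, N)
  ub <- matrix(0, N, N)
  for (j in seq_len(N)) {
    if (is.na(cls[j])) next
    b <- spec$bounds[[cls[j]]]
    lb[, j] <- b[1]
    ub[, j] <- b[2]
  }
  lb[!network$mask] <- 0
  ub[!network$mask] <- 0
  list(lb = lb, ub = ub)
}

#' Build a network with randomly initialized weights
#'
#' Weights are drawn uniformly from \code{(-init_scale, init_scale)} and
#' mapped into each connection's sign class (absolute value for excitatory,
#' negated absolute value for inhibitory, unchanged for unsigned input and
#' bias weights), then clipped into the class bounds.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param init_scale half-width of the uniform initialization (default 1).
#' @param seed optional integer seed.
#' @return an object of class \code{sah_network}.
#' @export
build_network <- function(spec = network_spec(), init_scale = 1, seed = NULL) {
  stopifnot(inherits(spec, "sah_network_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  mask <- build_mask(spec)
  N <- nrow(mask)
  cls <- column_classes(spec)
  W <- matrix(0, N, N, dimnames = dimnames(mask))
  u <- matrix(stats::runif(N * N, -init_scale, init_scale), N, N)
  for (j in seq_len(N)) {
    if (is.na(cls[j])) next
    w <- switch(cls[j], input = u[, j], excitatory = abs(u[, j]),
                inhibitory = -abs(u[, j]))
    b <- spec$bounds[[cls[j]]]
    W[, j] <- pmin(pmax(w, b[1]), b[2])
  }
  W[!mask] <- 0
  roles <- spec_roles(spec)
  net <- structure(list(spec = spec, mask = mask, weights = W,
                        unit_roles = roles,
                        unit_names = spec_unit_names(spec),
                        alive = rep(TRUE, N)),
                   class = "sah_network")
  validate_network(net)
  net
}

n_inputs <- function(network) {
  sum(network$unit_roles %in% c("task-input", "bias"))
}

hidden_idx <- function(network) {
  which(network$unit_roles %in% c("excitatory-hidden", "inhibitory-hidden"))
}

output_idx <- function(network) which(network$unit_roles == "output")

#' Logistic activation with offset and temperature
#'
#' @param net_input summed weighted input.
#' @param offset midpoint of the sigmoid (default 4).
#' @param temperature inverse slope (> 0, default 1).
#' @return \code{1 / (1 + exp(-(net_input - offset) / temperature))}.
#' @export
activation <- function(net_input, offset = 4, temperature = 1) {
  if (any(temperature <= 0)) stop("`temperature` must be > 0", call. = FALSE)
  1 / (1 + exp(-(net_input - offset) / temperature))
}

#' Advance the network one time-step
#'
#' Pure-R reference for the one-step-delay dynamics: every live non-input
#' unit's new activity is the activation of its weighted sum of the
#' previous-step activities; input units take the supplied input row
#' verbatim; dead units stay 0.
#'
#' @param network an \code{sah_network}.
#' @param activities current activity vector (length = number of units).
#' @param input_row task-input and bias values for this step.
#' @return the next activity vector.
#' @export
step_network <- function(network, activities, input_row) {
  N <- length(network$alive)
  ni <- n_inputs(network)
  if (length(activities) != N)
    stop("`activities` must have one entry per unit", call. = FALSE)
  if (length(input_row) != ni)
    stop(sprintf("`input_row` must have %d entries", ni), call. = FALSE)
  nxt <- numeric(N)
  nxt[seq_len(ni)] <- input_row
  for (i in seq_len(N)[-seq_len(ni)]) {
    if (!network$alive[i]) next
    nxt[i] <- activation(sum(network$weights[i, ] * activities),
                         network$spec$offset, network$spec$temperature)
  }
  nxt
}

#' Simulate a full episode
#'
#' Iterates the dynamics over all steps of an episode starting from the
#' given initial activities (default all zero) and returns the activity
#' trace of every unit.
#'
#' @param network an \code{sah_network}.
#' @param episode an \code{sah_episode} whose input columns match the
#'   network's input units, or a plain numeric matrix of input rows.
#' @param initial_activities starting state (default all zeros).
#' @return a (time x units) activity matrix with unit names as columns.
#' @export
run_episode <- function(network, episode, initial_activities = NULL) {
  inputs <- if (inherits(episode, "sah_episode")) episode$inputs else episode
  ni <- n_inputs(network)
  if (ncol(inputs) != ni)
    stop(sprintf("episode supplies %d input columns but the network has %d input units",
                 ncol(inputs), ni), call. = FALSE)
  N <- length(network$alive)
  init <- if (is.null(initial_activities)) numeric(N) else initial_activities
  if (length(init) != N)
    stop("`initial_activities` must have one entry per unit", call. = FALSE)
  A <- cpp_forward(network$weights, as.matrix(inputs), network$alive,
                   network$spec$offset, network$spec$temperature, init)
  colnames(A) <- network$unit_names
  A
}

#' Count present weights
#'
#' @param network an \code{sah_network}.
#' @return the number of unmasked, undeleted connections.
#' @export
count_weights <- function(network) sum(network$mask)

#' Count live hidden units
#'
#' @param network an \code{sah_network}.
#' @return the number of hidden units not removed by unit deletion.
#' @export
count_live_units <- function(network) sum(network$alive[hidden_idx(network)])

#' Validate a network's structural invariants
#'
#' Checks the connectivity rules (no self-connections, no
#' inhibitory-to-inhibitory links, inputs project only where allowed,
#' outputs project nowhere), that every present weight respects its
#' sign-class bounds or has magnitude below the class minimum only through
#' decay (magnitudes above the class maximum are never allowed), that
#' masked-out entries are exactly zero, and that dead units carry no
#' weights.
#'
#' @param network an \code{sah_network}.
#' @param strict if TRUE (default) signal an error on the first violation;
#'   otherwise return a character vector of violations.
#' @return TRUE invisibly (strict) or a character vector of problems.
#' @export
validate_network <- function(network, strict = TRUE) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  spec <- network$spec
  mask <- network$mask
  W <- network$weights
  allowed <- build_mask(spec)
  # deletions may only remove connections relative to the allowed template
  if (any(mask & !allowed)) note("mask allows a forbidden connection")
  if (any(W[!mask] != 0)) note("masked-out entries must be exactly zero")
  cls <- column_classes(spec)
  for (j in seq_len(ncol(W))) {
    if (is.na(cls[j])) next
    present <- mask[, j]
    if (!any(present)) next
    w <- W[present, j]
    b <- spec$bounds[[cls[j]]]
    if (cls[j] == "excitatory" && any(w < 0))
      note("negative weight leaving an excitatory unit")
    if (cls[j] == "inhibitory" && any(w > 0))
      note("positive weight leaving an inhibitory unit")
    if (any(abs(w) > max(abs(b)) + 1e-12))
      note(sprintf("weight magnitude above the %s class bound", cls[j]))
  }
  dead <- which(!network$alive)
  if (length(dead)) {
    if (any(mask[dead, , drop = FALSE]) || any(mask[, dead, drop = FALSE]))
      note("dead units must carry no connections")
    if (any(network$unit_roles[dead] %in% c("task-input", "bias", "output")))
      note("only hidden units may be deleted")
  }
  if (strict) {
    if (length(problems)) stop(paste(problems, collapse = "; "), call. = FALSE)
    return(invisible(TRUE))
  }
  problems
}

#' @export
print.sah_network <- function(x, ...) {
  cat(sprintf(
    "SAH network: %d task inputs%s, %d/%d live hidden units (%dE + %dI), %d outputs, %d weights\n",
    x$spec$n_task_inputs, if (x$spec$has_bias) " + bias" else "",
    count_live_units(x), x$spec$n_excitatory + x$spec$n_inhibitory,
    sum(x$alive & x$unit_roles == "excitatory-hidden"),
    sum(x$alive & x$unit_roles == "inhibitory-hidden"),
    x$spec$n_outputs, count_weights(x)))
  invisible(x)
}

#' Change the activation temperature
#'
#' Returns a copy of the network with a new inverse-slope parameter for all
#' units, used for attractor bifurcation analyses.
#'
#' @param network an \code{sah_network}.
#' @param temperature new temperature (> 0).
#' @export
set_temperature <- function(network, temperature) {
  stopifnot(temperature > 0)
  network$spec$temperature <- temperature
  network
}

network_format <- "sahnet-network"
network_format_version <- 1L

#' Save a network to a JSON file
#'
#' The file is a versioned, lossless JSON description of the network
#' (specification, unit roles, alive flags, connection mask and weights);
#' \code{\link{load_network}} restores it field-for-field.
#'
#' @param network an \code{sah_network}.
#' @param path output file path.
#' @export
save_network <- function(network, path) {
  doc <- list(format = network_format, version = network_format_version,
              spec = unclass(network$spec),
              unit_names = network$unit_names,
              unit_roles = network$unit_roles,
              alive = network$alive,
              mask = network$mask * 1L,
              weights = network$weights)
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load a network from a JSON file
#'
#' @param path path to a file written by \code{\link{save_network}}.
#' @return an \code{sah_network}.
#' @export
load_network <- function(path) {
  force(path)
  if (!is.character(path) || !file.exists(path))
    stop("network file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("cannot parse network file: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$format) || doc$format != network_format)
    stop("not a ", network_format, " file (field `format`)", call. = FALSE)
  if (is.null(doc$version) || doc$version != network_format_version)
    stop(sprintf("unsupported network file version `%s` (field `version`)",
                 paste(doc$version, collapse = ",")), call. = FALSE)
  for (f in c("spec", "unit_roles", "alive", "mask", "weights"))
    if (is.null(doc[[f]]))
      stop(sprintf("network file is missing field `%s`", f), call. = FALSE)
  sp <- doc$spec
  bounds <- lapply(sp$bounds, as.numeric)
  spec <- network_spec(n_task_inputs = sp$n_task_inputs,
                       n_excitatory = sp$n_excitatory,
                       n_inhibitory = sp$n_inhibitory,
                       n_outputs = sp$n_outputs, offset = sp$offset,
                       temperature = sp$temperature, bounds = bounds,
                       has_bias = sp$has_bias)
  W <- as.matrix(doc$weights)
  mask <- as.matrix(doc$mask) == 1
  nms <- if (!is.null(doc$unit_names)) as.character(doc$unit_names)
         else spec_unit_names(spec)
  dimnames(W) <- dimnames(mask) <- list(nms, nms)
  net <- structure(list(spec = spec, mask = mask, weights = W,
                        unit_roles = as.character(doc$unit_roles),
                        unit_names = nms,
                        alive = as.logical(doc$alive)),
                   class = "sah_network")
  validate_network(net)
  net
}
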