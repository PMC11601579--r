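# Pure-R reference implementations, independent of the package's C++ core,
# used as oracles for the dynamics and the BPTT gradient.

# Forward simulation written directly from the activity update rule.
r_forward <- function(network, inputs) {
  N <- length(network$alive)
  ni <- sum(network$unit_roles %in% c("task-input", "bias"))
  A <- matrix(0, nrow(inputs), N)
  prev <- rep(0, N)
  off <- network$spec$offset
  temp <- network$spec$temperature
  for (t in seq_len(nrow(inputs))) {
    cur <- rep(0, N)
    cur[seq_len(ni)] <- inputs[t, ]
    for (i in seq_len(N)[-seq_len(ni)]) {
      if (!network$alive[i]) next
      cur[i] <- 1 / (1 + exp(-((sum(network$weights[i, ] * prev) - off) / temp)))
    }
    A[t, ] <- cur
    prev <- cur
  }
  A
}

# MSE objective evaluated through the pure-R forward pass.
r_mse <- function(network, episode) {
  A <- r_forward(network, episode$inputs)
  oidx <- which(network$unit_roles == "output")
  out <- A[episode$valid, oidx, drop = FALSE]
  tg <- episode$targets[episode$valid, , drop = FALSE]
  mean((out - tg)^2)
}

# Central finite-difference gradient of the MSE w.r.t. every present weight.
r_fd_gradient <- function(network, episode, h = 1e-5) {
  G <- matrix(0, nrow(network$weights), ncol(network$weights))
  for (k in which(network$mask)) {
    np <- network; np$weights[k] <- np$weights[k] + h
    nm <- network; nm$weights[k] <- nm$weights[k] - h
    G[k] <- (r_mse(np, episode) - r_mse(nm, episode)) / (2 * h)
  }
  G
}

# Small dual-task network spec for fast gradient checks.
small_spec <- function(nE = 2, nI = 1, n_task = 3, n_out = 2) {
  network_spec(n_task_inputs = n_task, n_excitatory = nE, n_inhibitory = nI,
               n_outputs = n_out)
}

# A network hard-wired to hold both outputs at 0.5: all connections removed
# except the bias-to-output weights, set to the activation offset.
constant_half_network <- function() {
  net <- build_network(network_spec(), seed = 1)
  oidx <- which(net$unit_roles == "output")
  bias <- which(net$unit_roles == "bias")
  net$mask[] <- FALSE
  net$weights[] <- 0
  net$mask[oidx, bias] <- TRUE
  net$weights[oidx, bias] <- net$spec$offset
  net
}
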