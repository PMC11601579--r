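# Trained-network fixtures, built once per test session and shared across
# test files. Seeds are fixed so runs are reproducible.

.trained_cache <- new.env(parent = emptyenv())

# Full 13,500-epoch training-and-reduction run for one common-mode level.
trained_run <- function(alpha, net_seed = 42) {
  key <- sprintf("full_%s_%d", format(alpha), net_seed)
  if (!is.null(.trained_cache[[key]])) return(.trained_cache[[key]])
  task <- task_config(alpha = alpha)
  net <- build_network(network_spec(), seed = net_seed)
  res <- run_reduction_schedule(net, task,
                                seed = round(1000 + 100 * alpha) + net_seed)
  .trained_cache[[key]] <- res
  res
}

# 5,000-epoch (unreduced) network for one common-mode level.
trained_5k <- function(alpha, net_seed = 42) {
  key <- sprintf("5k_%s_%d", format(alpha), net_seed)
  if (!is.null(.trained_cache[[key]])) return(.trained_cache[[key]])
  task <- task_config(alpha = alpha)
  net <- build_network(network_spec(), seed = net_seed)
  res <- train(net, task, 5000,
               training_config(eval_every = 1000),
               seed = round(7000 + 1000 * alpha) + net_seed)
  .trained_cache[[key]] <- res
  res
}

# Trained single-input sample-and-hold network (Gate, Signal1, Bias -> 1 output).
trained_single_input <- function() {
  key <- "single"
  if (!is.null(.trained_cache[[key]])) return(.trained_cache[[key]])
  task <- task_config(alpha = 0, n_signals = 1)
  net <- build_network(network_spec(n_task_inputs = 2, n_outputs = 1), seed = 7)
  res <- train(net, task, 5000, seed = 707)
  .trained_cache[[key]] <- res
  res
}
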