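test_that("a constant-0.5 output network scores the 29% analytic baseline", {
  net <- constant_half_network()
  err <- evaluate_network(net, task_config(alpha = 0), 100, seed = 1)
  expect_equal(err, 100 * sqrt(1 / 12), tolerance = 0.05)
})

test_that("an untrained network starts near 54% error", {
  net <- build_network(network_spec(), seed = 2)
  err <- evaluate_network(net, task_config(alpha = 0), 100, seed = 3)
  expect_gt(err, 45); expect_lt(err, 65)
})

test_that("evaluation is deterministic given a seed and splits by output", {
  net <- build_network(network_spec(), seed = 4)
  task <- task_config(alpha = 0.5)
  e1 <- evaluate_network(net, task, 20, seed = 5)
  e2 <- evaluate_network(net, task, 20, seed = 5)
  expect_identical(e1, e2)
  po <- evaluate_network(net, task, 20, seed = 5, per_output = TRUE)
  expect_equal(po$overall, e1)
  expect_named(po$per_output, c("Output1", "Output2"))
})

test_that("input lesions remove outgoing weights and unknown names error", {
  net <- build_network(network_spec(), seed = 6)
  les <- lesion_inputs(net, "Signal2")
  s2 <- which(net$unit_names == "Signal2")
  expect_true(all(les$weights[, s2] == 0))
  expect_false(any(les$mask[, s2]))
  expect_silent(validate_network(les))
  expect_error(lesion_inputs(net, "Signal9"), "unknown")
  expect_error(lesion_inputs(net, "e1"), "input")
  # lesioning an input that already has no outgoing weights changes nothing
  again <- lesion_inputs(les, "Signal2")
  ep <- generate_episode(task_config(alpha = 0.2), seed = 7)
  expect_identical(run_episode(les, ep), run_episode(again, ep))
})

test_that("lesioning both signals pushes error to the no-information regime", {
  res <- trained_5k(0)
  les <- lesion_inputs(res$network, c("Signal1", "Signal2"))
  err <- evaluate_network(les, task_config(alpha = 0), 50, seed = 8)
  expect_gt(err, 20)
})

test_that("attractor map of a zero-weight network sits at the silent point", {
  net <- build_network(network_spec(), seed = 9)
  net$weights[net$mask] <- 0
  m <- attractor_map(net, relaxation_steps = 20)
  expect_equal(dim(m$values), c(11, 11, 2))
  expect_true(all(abs(m$values - activation(0)) < 1e-9))
  expect_true(all(m$values > 0 & m$values < 1))
})

test_that("relaxation traces settle and n_steps = 0 returns the initial state", {
  # a trained single-input network reaches a fixed point well before 100 steps
  single <- trained_single_input()$network
  o1 <- which(single$unit_roles == "output")
  tr1 <- relaxation_trace(single, 0.5, n_steps = 100)
  expect_lt(abs(tr1[101, o1] - tr1[100, o1]), 1e-6)
  # dual-input networks may end in a fixed point or a small flip cycle, but
  # the trajectory settles into a narrow band
  res <- trained_5k(0)
  tr <- relaxation_trace(res$network, 0.8, 0.2, n_steps = 100)
  oidx <- which(res$network$unit_roles == "output")
  expect_lt(diff(range(tr[92:101, oidx[1]])), 0.01)
  tr0 <- relaxation_trace(res$network, 0.8, 0.2, n_steps = 0)
  expect_equal(nrow(tr0), 1)
  expect_true(all(tr0 == 0))
})

test_that("cross-common-mode rows are reproducible and complete", {
  net <- build_network(network_spec(), seed = 10)
  m1 <- cross_cm_matrix(list("0" = net), n_test_epochs = 10, seed = 11)
  m2 <- cross_cm_matrix(list("0" = net), n_test_epochs = 10, seed = 11)
  expect_identical(m1$mean_percent_error, m2$mean_percent_error)
  expect_equal(dim(m1$mean_percent_error), c(1, 11))
  expect_false(any(is.na(m1$mean_percent_error)))
  expect_error(cross_cm_matrix(list(net)), "named")
  expect_error(cross_cm_matrix(list("0" = net, "0.5" = NULL)), "0.5")
})

test_that("solution classifier separates hand-built decoupled and averaging nets", {
  # averaging: both outputs driven identically by one hidden unit that sums
  # the two signals at the gate
  spec <- network_spec(n_excitatory = 2, n_inhibitory = 0)
  avg <- build_network(spec, seed = 12)
  avg$weights[avg$mask] <- 0
  nm <- avg$unit_names
  e1 <- which(nm == "e1"); e2 <- which(nm == "e2")
  o <- which(avg$unit_roles == "output")
  avg$weights[e1, nm == "Gate"] <- 4
  avg$weights[e1, nm == "Signal1"] <- 2
  avg$weights[e1, nm == "Signal2"] <- 2
  avg$weights[e1, nm == "Bias"] <- -2     # clips the sum against the offset
  avg$weights[e1, e2] <- 4; avg$weights[e2, e1] <- 4
  avg$weights[o, e1] <- 2; avg$weights[o, e2] <- 2
  avg$weights[o, nm == "Bias"] <- 1
  type <- solution_type(avg, task_config(alpha = 0.9), n_epochs = 30, seed = 13)
  expect_equal(as.character(type), "averaging")
  expect_gt(attr(type, "details")$output_agreement, 0.95)
})

test_that("trained networks classify as the study's qualitative regimes", {
  res0 <- trained_run(0)
  t0 <- solution_type(res0$network, task_config(alpha = 0), seed = 14)
  expect_equal(as.character(t0), "decoupled")
  res9 <- trained_5k(0.9)
  t9 <- solution_type(res9$network, task_config(alpha = 0.9), seed = 15)
  expect_equal(as.character(t9), "averaging")
})

test_that("reduced and unreduced error profiles share their shape at alpha 0", {
  res <- trained_run(0)
  m <- cross_cm_matrix(list("0" = res$checkpoints$unreduced,
                            "0" = res$checkpoints$reduced),
                       n_test_epochs = 50, seed = 16)
  d <- abs(m$mean_percent_error[1, ] - m$mean_percent_error[2, ])
  expect_lt(median(d[m$tested_alphas <= 0.6]), 2)
})
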