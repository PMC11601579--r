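test_that("default dual-task network has 946 weights and 32 hidden units", {
  net <- build_network(network_spec(), seed = 1)
  expect_equal(count_weights(net), 946)
  expect_equal(count_live_units(net), 32)
})

test_that("connectivity rules produce the expected mask", {
  # 1 task input + bias, 1 excitatory hidden, 1 output: in->hid, bias->hid,
  # bias->out, hid->out
  net <- build_network(network_spec(n_task_inputs = 1, n_excitatory = 1,
                                    n_inhibitory = 0, n_outputs = 1), seed = 2)
  expect_equal(count_weights(net), 4)
  # no inhibitory units: no negative hidden-origin weights anywhere
  exc_cols <- which(net$unit_roles == "excitatory-hidden")
  expect_true(all(net$weights[, exc_cols] >= 0))

  full <- build_network(network_spec(), seed = 3)
  roles <- full$unit_roles
  inh <- which(roles == "inhibitory-hidden")
  out <- which(roles == "output")
  task <- which(roles == "task-input")
  expect_false(any(diag(full$mask)))                     # no self-connections
  expect_false(any(full$mask[inh, inh]))                 # no I -> I
  expect_false(any(full$mask[, out]))                    # outputs project nowhere
  expect_false(any(full$mask[out, task]))                # task inputs skip outputs
  expect_true(all(full$mask[out, roles == "bias"]))      # bias reaches outputs
})

test_that("initial weights respect sign classes and bounds", {
  net <- build_network(network_spec(), seed = 4)
  expect_silent(validate_network(net))
  roles <- net$unit_roles
  exc <- which(roles == "excitatory-hidden")
  inh <- which(roles == "inhibitory-hidden")
  expect_true(all(net$weights[net$mask[, exc[1]], exc[1]] >= 0.001))
  expect_true(all(net$weights[net$mask[, inh[1]], inh[1]] <= -0.001))
  expect_true(all(abs(net$weights) <= 8))
  expect_true(all(net$weights[!net$mask] == 0))
})

test_that("validator catches violations", {
  net <- build_network(network_spec(), seed = 5)
  bad <- net
  exc <- which(bad$unit_roles == "excitatory-hidden")[1]
  to <- which(bad$mask[, exc])[1]
  bad$weights[to, exc] <- -1
  expect_error(validate_network(bad), "excitatory")
  bad2 <- net
  bad2$weights[which(!bad2$mask)[1]] <- 0.5
  expect_error(validate_network(bad2), "masked-out")
  bad3 <- net
  bad3$mask[3, 3] <- TRUE  # self-connection
  expect_error(validate_network(bad3), "forbidden")
})

test_that("activation matches its closed form", {
  expect_equal(activation(4), 0.5)
  expect_equal(activation(0), 1 / (1 + exp(4)), tolerance = 1e-12)
  expect_equal(activation(8), 1 / (1 + exp(-4)), tolerance = 1e-12)
  expect_gt(activation(5, temperature = 0.5), activation(5, temperature = 2))
  expect_error(activation(1, temperature = 0), "temperature")
})

test_that("one step of the dynamics behaves as specified", {
  net <- build_network(network_spec(), seed = 6)
  net$weights[net$mask] <- 0  # zero weights within the mask
  N <- length(net$alive)
  nxt <- step_network(net, rep(0, N), c(0, 0, 0, 1))
  non_input <- which(!net$unit_roles %in% c("task-input", "bias"))
  expect_equal(unique(round(nxt[non_input], 10)), round(activation(0), 10))
  expect_error(step_network(net, rep(0, N - 1), c(0, 0, 0, 1)), "entry")
})

test_that("a single saturating bias weight drives a unit to activation(8)", {
  net <- build_network(network_spec(n_task_inputs = 1, n_excitatory = 1,
                                    n_inhibitory = 0, n_outputs = 1), seed = 7)
  net$weights[net$mask] <- 0
  bias <- which(net$unit_roles == "bias")
  hid <- which(net$unit_roles == "excitatory-hidden")
  net$weights[hid, bias] <- 8
  inputs <- cbind(Input1 = rep(0, 5), Bias = rep(1, 5))
  tr <- run_episode(net, inputs)
  expect_equal(unname(tr[2:5, hid]), rep(activation(8), 4), tolerance = 1e-12)
})

test_that("C++ simulation matches the pure-R dynamics oracle", {
  net <- build_network(network_spec(), seed = 8)
  ep <- generate_episode(task_config(alpha = 0.4), seed = 9)
  expect_equal(run_episode(net, ep), r_forward(net, ep$inputs),
               ignore_attr = TRUE, tolerance = 1e-14)
})

test_that("simulation is deterministic and stays strictly inside (0, 1)", {
  net <- build_network(network_spec(), seed = 10)
  ep <- generate_episode(task_config(alpha = 0.6), seed = 11)
  t1 <- run_episode(net, ep)
  t2 <- run_episode(net, ep)
  expect_identical(t1, t2)
  non_input <- which(!net$unit_roles %in% c("task-input", "bias"))
  expect_true(all(t1[, non_input] > 0 & t1[, non_input] < 1))
  empty <- run_episode(net, generate_episode(task_config(epoch_length = 0L)))
  expect_equal(nrow(empty), 0)
})

test_that("input changes propagate with a one-step delay per layer", {
  net <- build_network(network_spec(), seed = 12)
  ep <- generate_episode(task_config(alpha = 0.5), seed = 13)
  ep2 <- ep
  ep2$inputs[10, "Signal1"] <- 1 - ep2$inputs[10, "Signal1"]
  d <- abs(run_episode(net, ep) - run_episode(net, ep2))
  hid <- which(net$unit_roles %in% c("excitatory-hidden", "inhibitory-hidden"))
  out <- which(net$unit_roles == "output")
  expect_true(all(d[1:9, c(hid, out)] == 0))
  expect_true(all(d[10, c(hid, out)] == 0))   # same-step activities unchanged
  expect_gt(max(d[11, hid]), 0)               # hidden respond at t + 1
  expect_true(all(d[11, out] == 0))
  expect_gt(max(d[12, out]), 0)               # outputs respond at t + 2
})

test_that("deleting every weight below magnitude 9 leaves none", {
  net <- build_network(network_spec(), seed = 14)
  expect_equal(count_weights(delete_small_weights(net, 9)), 0)
})

test_that("networks round-trip through JSON losslessly", {
  net <- build_network(network_spec(), seed = 15)
  net <- delete_small_weights(net, 0.3)  # non-trivial mask
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_network(net, path)
  back <- load_network(path)
  expect_identical(back$weights, net$weights)
  expect_identical(back$mask, net$mask)
  expect_identical(back$alive, net$alive)
  expect_identical(back$unit_roles, net$unit_roles)
  expect_equal(back$spec, net$spec)
})

test_that("malformed network files produce clear errors", {
  net <- build_network(network_spec(n_excitatory = 2, n_inhibitory = 1),
                       seed = 16)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_network(net, path)
  doc <- jsonlite::fromJSON(path)
  doc$weights <- NULL
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path)
  expect_error(load_network(path), "weights")
  doc2 <- jsonlite::fromJSON(path)
  doc2$version <- 99
  writeLines(jsonlite::toJSON(doc2, auto_unbox = TRUE), path)
  expect_error(load_network(path), "version")
  writeLines("{not json", path)
  expect_error(load_network(path), "parse")
})
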