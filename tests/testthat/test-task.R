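test_that("task config validates its arguments", {
  expect_error(task_config(alpha = -0.1), "alpha")
  expect_error(task_config(alpha = 1.5), "alpha")
  expect_error(task_config(gate_spacing_min = 5, gate_spacing_max = 3),
               "gate_spacing")
  expect_error(task_config(target_delay = 20, epoch_length = 20),
               "target_delay")
  expect_error(task_config(n_signals = 3), "n_signals")
})

test_that("episode structure follows the task definition", {
  cfg <- task_config(alpha = 0.5)
  ep <- generate_episode(cfg, seed = 1)
  expect_identical(colnames(ep$inputs), c("Gate", "Signal1", "Signal2", "Bias"))
  expect_true(all(ep$inputs[, "Gate"] %in% c(0, 1)))
  expect_true(all(ep$inputs[, "Bias"] == 1))
  sig <- ep$inputs[, c("Signal1", "Signal2")]
  expect_true(all(sig >= 0 & sig <= 1))
  # a gate fires at the first step so samples are defined from the start
  expect_equal(unname(ep$inputs[1, "Gate"]), 1)
  expect_identical(ep$valid, c(FALSE, FALSE, rep(TRUE, 18)))
})

test_that("gate pulses are spaced 3 to 6 steps apart", {
  cfg <- task_config(alpha = 0, epoch_length = 1000L)
  ep <- generate_episode(cfg, seed = 2)
  gaps <- diff(which(ep$inputs[, "Gate"] == 1))
  expect_true(all(gaps >= 3 & gaps <= 6))
  expect_true(length(unique(gaps)) > 1)
})

test_that("held samples are piecewise constant and targets are delayed samples", {
  for (seed in 1:5) {
    cfg <- task_config(alpha = 0.3, epoch_length = 50L)
    ep <- generate_episode(cfg, seed = seed)
    gate <- ep$inputs[, "Gate"]
    for (k in 1:2) {
      s <- ep$samples[, k]
      # changes only at gate steps, where the sample takes the signal value
      changed <- which(diff(s) != 0) + 1L
      expect_true(all(gate[changed] == 1))
      at_gates <- which(gate == 1)
      expect_equal(s[at_gates], ep$inputs[at_gates, k + 1L])
      # target k at step t equals held sample k at t - delay, exhaustively
      d <- cfg$target_delay
      expect_equal(ep$targets[(d + 1):50, k], s[1:(50 - d)])
      expect_true(all(is.na(ep$targets[1:d, k])))
    }
  }
})

test_that("alpha = 1 makes the two signals identical, alpha = 0 independent", {
  ep1 <- generate_episode(task_config(alpha = 1, epoch_length = 200L), seed = 3)
  expect_equal(ep1$inputs[, "Signal1"], ep1$inputs[, "Signal2"])
  ep0 <- generate_episode(task_config(alpha = 0, epoch_length = 10000L), seed = 4)
  expect_lt(abs(cor(ep0$inputs[, "Signal1"], ep0$inputs[, "Signal2"])), 0.05)
})

test_that("signal mean matches the analytic value alpha^2/2 + (1-alpha)/2", {
  # at alpha = 0.5 the construction gives E[S] = 0.125 + 0.25 = 0.375
  ep <- generate_episode(task_config(alpha = 0.5, epoch_length = 10000L),
                         seed = 5)
  sdev <- sqrt(0.5^4 / 12 + 0.5^2 / 12)
  se <- sdev / sqrt(10000)
  expect_lt(abs(mean(ep$inputs[, "Signal1"]) - 0.375), 3 * se)
  expect_lt(abs(mean(ep$inputs[, "Signal2"]) - 0.375), 3 * se)
})

test_that("signals never leave [0, 1] across the alpha range", {
  for (a in c(0, 0.3, 0.7, 1)) {
    ep <- generate_episode(task_config(alpha = a, epoch_length = 250000L),
                           seed = 100 + 10 * a)
    sig <- ep$inputs[, c("Signal1", "Signal2")]
    expect_gte(min(sig), 0)
    expect_lte(max(sig), 1)
  }
})

test_that("signal correlation matches a direct Monte-Carlo oracle and grows with alpha", {
  expect_equal(signal_correlation(1, 1000, seed = 6), 1.0)
  expect_lt(abs(signal_correlation(0, 10000, seed = 7)), 0.05)
  # independent oracle: simulate the construction directly
  set.seed(8)
  a <- 0.5
  n <- 200000
  C <- runif(n, 0, a)
  r_oracle <- cor(a * C + runif(n, 0, 1 - a), a * C + runif(n, 0, 1 - a))
  r <- signal_correlation(0.5, 100000, seed = 9)
  expect_gt(r, 0); expect_lt(r, 1)
  expect_lt(abs(r - r_oracle), 0.02)
  rs <- sapply(c(0, 0.25, 0.5, 0.75, 1),
               function(a) signal_correlation(a, 10000, seed = 10))
  expect_true(all(diff(rs) > -0.02))
  expect_error(signal_correlation(0.5, n_steps = 50), "n_steps")
})

test_that("episode seeding is reproducible and streams do not overlap", {
  cfg <- task_config(alpha = 0.4)
  e1 <- generate_episode(cfg, seed = 11)
  e2 <- generate_episode(cfg, seed = 11)
  expect_identical(e1$inputs, e2$inputs)
  eps <- generate_episodes(cfg, 5, seed = 12)
  sigs <- sapply(eps, function(e) e$inputs[1, "Signal1"])
  expect_equal(length(unique(sigs)), 5)
})

test_that("episodes export to CSV with one row per step", {
  ep <- generate_episode(task_config(alpha = 0.2), seed = 13)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_episode_csv(ep, path)
  d <- read.csv(path)
  expect_equal(nrow(d), 20)
  expect_identical(names(d), c("step", "gate", "signal1", "signal2", "bias",
                               "target1", "target2", "valid"))
  expect_equal(d$signal1, unname(ep$inputs[, "Signal1"]))
})

test_that("zero-length episodes are well-formed", {
  ep <- generate_episode(task_config(epoch_length = 0L), seed = 14)
  expect_equal(nrow(ep$inputs), 0)
  expect_length(ep$valid, 0)
})
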