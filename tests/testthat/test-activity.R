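test_that("pair sampling matches the binomial expectation", {
  g0 <- build_groups(50, p_pair = 0, seed = 1)
  expect_equal(nrow(g0$pairs), 0)
  expect_true(all(lengths(g0$membership) == 0))
  g1 <- build_groups(10, p_pair = 1, seed = 1, group_mode = "pairs")
  expect_equal(nrow(g1$pairs), choose(10, 2))
  expect_true(all(lengths(g1$membership) == 9))
  # empirical pair count over 100 seeds within 3 s.e. of C(100,2) * 0.05
  counts <- vapply(1:100, function(s)
    nrow(build_groups(100, 0.05, seed = s)$pairs), 1)
  m <- choose(100, 2) * 0.05
  se <- sqrt(choose(100, 2) * 0.05 * 0.95 / 100)
  expect_lt(abs(mean(counts) - m), 3 * se)
  # pairs are unique and ordered
  g <- build_groups(40, 0.2, seed = 7)
  expect_true(all(g$pairs[, 1] < g$pairs[, 2]))
  expect_false(any(duplicated(g$pairs)))
})

test_that("component groups collect paired neurons into shared processes", {
  g <- build_groups(60, 0.1, group_mode = "components", seed = 2)
  # every neuron belongs to at most one component group
  expect_true(all(lengths(g$membership) <= 1))
  # paired neurons always share a group
  for (r in seq_len(nrow(g$pairs))) {
    a <- g$pairs[r, 1]; b <- g$pairs[r, 2]
    expect_equal(g$membership[[a]], g$membership[[b]])
  }
})

test_that("spike counts follow the configured total rate", {
  g <- build_groups(200, 0.05, seed = 3)
  expect_length(simulate_spikes(g, duration = 0, seed = 1)$spikes[[1]], 0)
  sp <- simulate_spikes(g, total_rate = 0.3, duration = 300,
                        shared_rate = 0.0123, seed = 4)
  counts <- lengths(sp$spikes)
  # expected 90 spikes per neuron; mean over 200 neurons within 3 s.e.
  expect_lt(abs(mean(counts) - 90), 3 * sqrt(90 / 200) + 1)
  expect_true(all(abs(sp$rates$configured_total - 0.3) < 1e-12))
  expect_error(simulate_spikes(g, total_rate = -1), "non-negative")
})

test_that("clamping warns when shared processes exceed the total rate", {
  g <- build_groups(10, 1, group_mode = "pairs", seed = 1)  # 9 groups each
  expect_warning(simulate_spikes(g, total_rate = 0.3, shared_rate = 0.2,
                                 duration = 10, seed = 1), "clamped")
})

test_that("shared-pair count correlation matches the common-shock formula", {
  # two neurons, one shared group: corr of binned counts ~ r_s / r_total
  g <- build_groups(2, 1, group_mode = "pairs", seed = 1)
  rs <- 0.15
  reps <- vapply(1:60, function(s) {
    sp <- simulate_spikes(g, total_rate = 0.3, duration = 200,
                          shared_rate = rs, seed = s)
    a <- tabulate(sp$spikes[[1]], sp$n_bins)
    b <- tabulate(sp$spikes[[2]], sp$n_bins)
    suppressWarnings(cor(a, b))
  }, 1)
  expect_lt(abs(mean(reps) - rs / 0.3), 3 * sd(reps) / sqrt(60) + 0.005)
})

test_that("sensor kernel converts spikes to fluorescence correctly", {
  sensor <- sensor_params(rise_ms = 2, half_decay_ms = 70, unitary_dff = 0.4,
                          baseline = 2)
  # no spikes: constant baseline
  sp0 <- structure(list(spikes = list(integer(0)), n_bins = 1000, dt = 1e-3,
                        duration = 1), class = "spike_set")
  f0 <- spikes_to_fluorescence(sp0, sensor)
  expect_equal(as.numeric(f0), rep(2, 1000))
  # single spike: matches the direct convolution oracle, peak = 0.4 dF/F
  sp1 <- structure(list(spikes = list(50L), n_bins = 2000, dt = 1e-3,
                        duration = 2), class = "spike_set")
  f1 <- spikes_to_fluorescence(sp1, sensor)
  tau_r <- 2e-3; tau_d <- 70e-3 / log(2)
  tt <- (0:1999) * 1e-3
  k <- exp(-tt / tau_d) - exp(-tt / tau_r)
  k <- k * 0.4 / max(k)
  oracle <- 2 * (1 + c(rep(0, 49), k[1:(2000 - 49)]))
  expect_equal(as.numeric(f1), oracle, tolerance = 1e-10)
  expect_equal(max(f1) / 2 - 1, 0.4, tolerance = 1e-6)
  # superposition: two far-apart spikes equal the sum of shifted singles
  sp2 <- structure(list(spikes = list(c(50L, 1450L)), n_bins = 2500, dt = 1e-3,
                        duration = 2.5), class = "spike_set")
  f2 <- spikes_to_fluorescence(sp2, sensor)
  spA <- structure(list(spikes = list(50L), n_bins = 2500, dt = 1e-3,
                        duration = 2.5), class = "spike_set")
  spB <- structure(list(spikes = list(1450L), n_bins = 2500, dt = 1e-3,
                        duration = 2.5), class = "spike_set")
  fa <- spikes_to_fluorescence(spA, sensor)
  fb <- spikes_to_fluorescence(spB, sensor)
  expect_equal(as.numeric(f2), as.numeric(fa + fb - 2), tolerance = 1e-6)
})

test_that("pair statistics behave at the independence and identity limits", {
  x <- matrix(rnorm(300), 100, 3)
  x[, 2] <- x[, 1]
  st <- ground_truth_pair_statistics(x)
  cc <- cor(x)
  expect_equal(st$mean, mean(cc[upper.tri(cc)]))
  # identical traces give correlation 1 for that pair
  expect_equal(max(cc[upper.tri(cc)]), 1)
  # constant traces are excluded with a warning
  x[, 3] <- 5
  expect_warning(ground_truth_pair_statistics(x), "constant")
  # independent simulation: mean correlation near 0
  a <- simulate_activity(60, p_pair = 0, duration = 60, out_dt = 0.01,
                         seed = 9)
  st0 <- ground_truth_pair_statistics(a$traces)
  expect_lt(abs(st0$mean), 3 * st0$sd / sqrt(st0$n_pairs) + 0.01)
})

test_that("mean pair correlation increases with the shared rate", {
  ms <- vapply(c(0.004, 0.012, 0.03), function(rs) {
    mean(vapply(1:4, function(s) {
      a <- simulate_activity(80, shared_rate = rs, duration = 120,
                             out_dt = 0.01, seed = 100 + s)
      ground_truth_pair_statistics(a$traces)$mean
    }, 1))
  }, 1)
  expect_true(all(diff(ms) > 0))
})

test_that("activity sets are reproducible from the seed", {
  a1 <- simulate_activity(30, duration = 20, out_dt = 0.01, seed = 5)
  a2 <- simulate_activity(30, duration = 20, out_dt = 0.01, seed = 5)
  expect_identical(a1$traces, a2$traces)
  expect_identical(a1$spikes$spikes, a2$spikes$spikes)
})
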