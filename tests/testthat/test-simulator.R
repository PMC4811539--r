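test_that("sampling is deterministic under a fixed seed", {
  th <- msp_params(0.02, 30, 1.45, 1e-4)
  set.seed(42); a <- rmsp(500, th)
  set.seed(42); b <- rmsp(500, th)
  expect_identical(a, b)
})

test_that("constant-hazard sampling reproduces the exponential mean", {
  thc <- msp_params(1e-12, 100, 1.5, 1e-3)
  set.seed(43)
  x <- rmsp(1e5, thc)
  expect_equal(mean(x), 1000, tolerance = 0.01)
})

test_that("the empirical distribution matches the model law", {
  th <- msp_params(0.02, 30, 1.45, 1e-4)
  set.seed(44)
  x <- rmsp(1e5, th)
  expect_lt(ks_stat(x, function(q) pmsp(q, th)), 0.006)
  # probability-integral transform is uniform
  set.seed(45)
  u <- pmsp(rmsp(10000, th), th)
  expect_gt(burstfit:::.ks_pvalue(ks_stat(u, identity), 10000), 0.01)
})

test_that("a large sample shows the three regimes of the hazard", {
  th <- msp_params(0.01, 10, 1.4, 1e-6)
  set.seed(46)
  x <- rmsp(2e5, th)
  eb <- empirical_density_logbins(x, bins_per_decade = 10)
  # quick-response plateau: density near 0 close to lambda0 + lambda_inf
  head_bins <- eb[eb$tau < 1, ]
  expect_equal(mean(head_bins$density), 0.01, tolerance = 0.15)
  # intermediate log-log slope close to -alpha
  mid <- eb[eb$tau > 1e2 & eb$tau < 1e4 & eb$count > 0, ]
  slope <- coef(lm(log(density) ~ log(tau), data = mid))[2]
  expect_equal(unname(slope), -1.4, tolerance = 0.15)
  # exponential tail: beyond the power-law window the log density drops
  # linearly in tau with rate near lambda_inf
  tail_bins <- eb[eb$tau > 2e6 & eb$count > 3, ]
  if (nrow(tail_bins) >= 3) {
    rate <- -coef(lm(log(density) ~ tau, data = tail_bins))[2]
    expect_equal(unname(rate), 1e-6, tolerance = 0.5)
  }
})

test_that("population sampling respects the configuration and its truncations", {
  cfg <- population_config(n_users = 150, events_range = c(30, 60), seed = 77)
  coh <- sample_population(cfg)
  expect_length(coh$users, 150)
  pars <- t(vapply(coh$users, function(u) unclass(u$params)[1:4], numeric(4)))
  expect_true(all(pars > 0))
  expect_true(all(pars[, "alpha"] > cfg$alpha_min))
  expect_true(all(pars[, "lambda_inf"] >= cfg$lambda_inf_min))
  ns <- vapply(coh$users, function(u) length(u$tau), 1L)
  expect_true(all(ns >= 30 & ns <= 60))
  # same master seed, same cohort
  coh2 <- sample_population(cfg)
  expect_identical(coh$users[[7]]$tau, coh2$users[[7]]$tau)
})

test_that("the skew-normal burst-exponent draws target the configured mean", {
  set.seed(78)
  a <- burstfit:::.rskewnorm(2000, 1.45, 0.3, 4)
  expect_equal(mean(a), 1.45, tolerance = 0.05 / 1.45)
  expect_equal(sd(a), 0.3, tolerance = 0.1)
  expect_gt(mean((a - mean(a))^3), 0)   # right-skewed
})

test_that("over-tight truncation is reported as a configuration error", {
  cfg <- population_config(n_users = 2, alpha_mean = 0.1, alpha_sd = 0.01,
                           alpha_min = 3, events_range = c(5, 6), seed = 1)
  expect_error(sample_population(cfg), "rejection sampling")
})

test_that("event-log conversion is an exact round trip", {
  expect_equal(to_event_log(list(u1 = c(10, 15)))$time, c(0, 10, 25))
  cfg <- population_config(n_users = 5, events_range = c(10, 30), seed = 9)
  coh <- sample_population(cfg)
  log <- to_event_log(coh)
  iv <- intervals_from_timestamps(log, min_events = 0)
  for (u in coh$users)
    expect_equal(unname(iv[[u$id]]), u$tau, tolerance = 1e-12)
  # quantized timestamps perturb each interval by less than 1 s
  logq <- to_event_log(coh, quantize = TRUE)
  ivq <- intervals_from_timestamps(logq, min_events = 0)
  for (u in coh$users)
    expect_true(all(abs(unname(ivq[[u$id]]) - u$tau) < 1))
})
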