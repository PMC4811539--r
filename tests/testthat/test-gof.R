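test_that("KS statistic matches a brute-force evaluation and known cases", {
  # single observation at the model median
  expect_equal(ks_stat(10, function(q) pexp(q, log(2) / 10)), 0.5)
  set.seed(17)
  for (r in 1:50) {
    n <- sample(2:30, 1)
    x <- rexp(n, 1)
    expect_equal(ks_stat(x, pexp), ks_bruteforce(x, pexp), tolerance = 1e-14)
  }
  expect_error(ks_stat(c(1, 2), function(q) rev(pexp(q))), "monotone")
})

test_that("KS p-values reproduce the classical critical values", {
  # asymptotic 5% critical value at n = 100 is 1.358/sqrt(100)
  p_above <- burstfit:::.ks_pvalue(1.36 / sqrt(100), 100)
  p_below <- burstfit:::.ks_pvalue(1.35 / sqrt(100), 100)
  expect_lt(p_above, 0.05)
  expect_gt(p_below, 0.05)
  # exact small-n values agree with stats::ks.test
  set.seed(18)
  for (n in c(8, 30, 73)) {
    x <- rexp(n, 1)
    D <- ks_stat(x, pexp)
    expect_equal(burstfit:::.ks_pvalue(D, n),
                 suppressWarnings(ks.test(x, pexp)$p.value), tolerance = 1e-8)
  }
  # large-sample uniform draws stay under the asymptotic band
  set.seed(19)
  D <- ks_stat(runif(10000), identity)
  expect_lt(D, 0.025)
})

test_that("CvM statistic matches quadrature oracle and known cases", {
  expect_equal(burstfit:::.cvm_stat(10, function(q) pexp(q, log(2) / 10)), 1 / 12)
  set.seed(20)
  for (r in 1:20) {
    n <- sample(2:25, 1)
    x <- rexp(n, 1)
    expect_equal(burstfit:::.cvm_stat(x, pexp), cvm_quadrature(x, pexp),
                 tolerance = 1e-10)
  }
  # asymptotic null distribution hits the classical quantiles
  expect_equal(burstfit:::.cvm_cdf_asymptotic(0.461), 0.95, tolerance = 1e-3)
  expect_equal(burstfit:::.cvm_cdf_asymptotic(0.743), 0.99, tolerance = 1e-3)
})

test_that("chi-square test uses equal-probability bins and fitted-parameter dof", {
  set.seed(22)
  x <- rexp(1000, 0.01)
  f <- fit_baseline(x, "exponential")
  g <- gof_chisq(x, f)
  expect_equal(g$dof, min(1000 %/% 5, 50) - 1 - 1)
  expect_gte(g$statistic, 0)
  # observed counts exactly equal to expected give statistic 0:
  # 250 points, 50 bins, 5 points placed inside every equal-probability bin
  k <- 50
  pos <- as.vector(outer(c(0.1, 0.3, 0.5, 0.7, 0.9), seq_len(k) - 1, `+`)) / k
  x0 <- qexp(pos, 0.01)
  f0 <- structure(list(family = "exponential", params = c(rate = 0.01),
                       n = length(x0)), class = "baseline_fit")
  expect_equal(gof_chisq(x0, f0)$statistic, 0)
  expect_error(gof_chisq(x0[1:49], f0), "n >= 50")
})

test_that("tests reject a mis-specified exponential but pass the truth", {
  th <- msp_params(0.05, 60, 1.5, 1e-4)   # strongly bursty
  set.seed(23)
  rej_exp <- 0
  for (r in 1:20) {
    x <- rmsp(1000, th)
    fe <- fit_baseline(x, "exponential")
    if (!gof_ks(x, fe)$passed) rej_exp <- rej_exp + 1
  }
  expect_equal(rej_exp, 20)
  # chi-square power on the same configuration
  x <- rmsp(1000, th)
  expect_false(gof_chisq(x, fit_baseline(x, "exponential"))$passed)
})

test_that("probability-integral transform leaves the KS statistic unchanged", {
  th <- msp_params(0.02, 30, 1.45, 1e-4)
  set.seed(24)
  x <- rmsp(200, th)
  D1 <- ks_stat(x, function(q) pmsp(q, th))
  D2 <- ks_stat(pmsp(x, th), identity)
  expect_equal(D1, D2, tolerance = 1e-12)
})

test_that("population evaluation averages per-user results and is order-invariant", {
  cfg <- population_config(n_users = 4, events_range = c(120, 200), seed = 11)
  coh <- sample_population(cfg)
  series <- lapply(coh$users, `[[`, "tau")
  tab <- evaluate_population(series, families = c("exponential", "lognormal"),
                             n_starts = 2)
  tab_rev <- evaluate_population(rev(series), families = c("exponential", "lognormal"),
                                 n_starts = 2)
  expect_equal(tab$ks_stat, tab_rev$ks_stat, tolerance = 1e-12)
  expect_true(all(tab$ks_rate >= 0 & tab$ks_rate <= 1))
  # one-user cohort: averages equal that user's statistics
  one <- evaluate_population(series[1], families = "exponential", n_starts = 2)
  fe <- fit_baseline(series[[1]], "exponential")
  expect_equal(one$ks_stat, gof_ks(series[[1]], fe)$statistic)
  # pass rates cannot rise as the significance level rises
  t5 <- evaluate_population(series, families = "lognormal", level = 0.05, n_starts = 2)
  t1 <- evaluate_population(series, families = "lognormal", level = 0.01, n_starts = 2)
  expect_gte(t1$ks_rate, t5$ks_rate)
})

test_that("parametric bootstrap p-values are returned alongside classical ones", {
  set.seed(25)
  x <- rexp(120, 0.01)
  f <- fit_baseline(x, "exponential")
  g <- gof_ks(x, f, bootstrap = TRUE, n_boot = 39)
  expect_true(g$p_boot >= 0 && g$p_boot <= 1)
  expect_false(is.na(g$p_value))
})

test_that("crop curve at fraction zero matches the uncropped evaluation", {
  cfg <- population_config(n_users = 3, events_range = c(150, 250), seed = 13)
  coh <- sample_population(cfg)
  cc <- crop_curve(coh, families = "lognormal", crop_fractions = c(0, 0.2),
                   n_starts = 2)
  tab <- evaluate_population(coh, families = "lognormal", n_starts = 2)
  row0 <- cc[cc$fraction == 0, ]
  expect_equal(row0$mean_statistic, tab$ks_stat, tolerance = 1e-12)
  expect_true(is.finite(attr(cc, "multiscale_reference")))
})
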