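test_that("baseline densities take their closed-form values", {
  expect_equal(dexp(1000, 0.001), 0.001 * exp(-1))
  expect_equal(dpareto(1, xm = 1, exponent = 2.4), 1.4)
  expect_equal(dpareto(0.5, xm = 1, exponent = 2.4), 0)   # below support
  expect_equal(dlnorm(1, 0, 1), 1 / sqrt(2 * pi))
  # pareto p/q/r consistency
  expect_equal(ppareto(qpareto(c(0.2, 0.9), 10, 2.5), 10, 2.5), c(0.2, 0.9))
  set.seed(1)
  expect_gte(min(rpareto(1000, 10, 2.5)), 10)
})

test_that("closed-form maximum-likelihood fits are exact on hand-checkable data", {
  expect_equal(fit_baseline(c(1000, 3000), "exponential")$params[["rate"]], 1 / 2000)
  # Hill estimator on {1, e, e^2}: exponent = 1 + 3/3 = 2
  f <- fit_baseline(c(1, exp(1), exp(2)), "pareto", xm = 1)
  expect_equal(f$params[["exponent"]], 2)
  lx <- log(c(2, 5, 9))
  fl <- fit_baseline(c(2, 5, 9), "lognormal")
  expect_equal(fl$params[["meanlog"]], mean(lx))
  expect_equal(fl$params[["sdlog"]], sqrt(mean((lx - mean(lx))^2)))
})

test_that("weibull fit recovers shape and scale from a large sample", {
  set.seed(11)
  x <- rweibull(10000, shape = 0.6, scale = 500)
  f <- fit_baseline(x, "weibull")
  expect_equal(unname(f$params[["shape"]]), 0.6, tolerance = 0.03 / 0.6)
  expect_equal(unname(f$params[["scale"]]), 500, tolerance = 0.05)
})

test_that("zeros are dropped only for families whose support excludes them", {
  x <- c(0, 0, 1, 2, 3, 10)
  expect_equal(fit_baseline(x, "exponential")$n_dropped, 0)
  expect_equal(fit_baseline(x, "lognormal")$n_dropped, 2)
  expect_equal(fit_baseline(x, "pareto")$n_dropped, 2)
  expect_error(fit_baseline(rep(5, 10), "lognormal"), "degenerate")
})

test_that("each family's fit is a local maximum of its likelihood", {
  set.seed(21)
  x <- rlnorm(400, meanlog = 4, sdlog = 1.3)
  for (fam in c("exponential", "weibull", "lognormal", "pareto")) {
    fit <- fit_baseline(x, fam)
    ll_at <- function(p) {
      switch(fam,
        exponential = sum(dexp(fit$data, p[1], log = TRUE)),
        weibull = sum(dweibull(fit$data, p[1], p[2], log = TRUE)),
        lognormal = sum(dlnorm(fit$data, p[1], p[2], log = TRUE)),
        pareto = sum(dpareto(fit$data, fit$params[["xm"]], p[1], log = TRUE)))
    }
    p0 <- switch(fam,
                 exponential = fit$params[["rate"]],
                 weibull = unname(fit$params),
                 lognormal = unname(fit$params),
                 pareto = fit$params[["exponent"]])
    set.seed(31)
    for (r in 1:8) {
      pert <- p0 * exp(rnorm(length(p0), 0, 0.05))
      if (fam == "lognormal") pert[1] <- p0[1] + rnorm(1, 0, 0.05)
      expect_lte(ll_at(pert), ll_at(p0) + 1e-8)
    }
  }
})

test_that("cutoff tuning recovers the true Pareto lower bound", {
  set.seed(5)
  hits <- replicate(20, {
    x <- rpareto(5000, 10, 2.5)
    pareto_tune_xm(x, max_candidates = 200)$xm
  })
  # the true cutoff is the sample minimum; the tuned one should sit in the
  # first decile of the data in most replicates
  expect_lt(median(hits), qpareto(0.1, 10, 2.5))
})

test_that("cutoff tuning on multiscale data crops a substantial head", {
  th <- msp_params(0.05, 60, 1.5, 1e-4)
  set.seed(6)
  x <- rmsp(3000, th)
  res <- pareto_tune_xm(x, max_candidates = 150)
  expect_gt(res$cropped_fraction, 0.1)
  # a single candidate at the minimum means no cropping
  xm0 <- min(x[x > 0])
  f0 <- fit_baseline(x, "pareto", xm = xm0)
  expect_equal(f0$n_dropped, 0)
})

test_that("power-law hazard special cases reduce to Pareto and Weibull", {
  # alpha_h = 1: exactly Pareto with exponent 1 + gamma
  expect_equal(dpowhaz(10, gamma = 1.4, alpha_h = 1, tau_min = 1), 1.4 * 10^-2.4)
  g <- 10^seq(0, 4, length.out = 20)
  expect_equal(dpowhaz(g, 1.4, 1, tau_min = 1),
               dpareto(g, xm = 1, exponent = 2.4), tolerance = 1e-12)
  # alpha_h = 0.5, gamma = 1: Weibull with shape 0.5, measured from tau_min
  tau_min <- 1e-9
  shape <- 0.5
  scale <- (shape / 1)^(1 / shape)       # gamma = shape / scale^shape
  g2 <- seq(0.5, 10, length.out = 20)
  ratio <- dpowhaz(g2, 1, 0.5, tau_min) / dweibull(g2, shape, scale)
  # survival measured from tau_min contributes a constant factor -> compare shapes
  expect_equal(ratio / ratio[1], rep(1, 20), tolerance = 1e-6)
  expect_equal(dpowhaz(2, 1.7, 1, tau_min = 2), 1.7 / 2)  # density = hazard at tau_min
  expect_error(dpowhaz(1, 1, 1, tau_min = 0), "tau_min")
})
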