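test_that("parameter validation enforces strict positivity and flags large tail rates", {
  expect_error(msp_params(0, 100, 1.5, 1e-4), "strictly positive")
  expect_error(msp_params(0.1, -1, 1.5, 1e-4), "strictly positive")
  expect_error(msp_params(0.1, 100, NA, 1e-4), "finite")
  th <- msp_params(1e-4, 100, 1.5, 1e-3)
  expect_match(attr(th, "diagnostics"), "lambda_inf >= lambda0")
  expect_null(attr(msp_params(0.1, 100, 1.5, 1e-4), "diagnostics"))
})

test_that("intensity has the plateau, half-way point and tail limit", {
  th <- msp_params(0.1, 100, 1.5, 1e-4)
  expect_equal(hmsp(0, th), 0.1001)
  expect_equal(hmsp(100, th), 0.0501)
  expect_equal(hmsp(1e9, th), 1e-4, tolerance = 1e-6)
  expect_error(hmsp(-1, th), "nonnegative")
  # monotone nonincreasing
  g <- 10^seq(-2, 8, length.out = 300)
  expect_true(all(diff(hmsp(g, th)) <= 0))
})

test_that("cumulative hazard matches the alpha = 1 and alpha = 2 closed forms", {
  floorv <- 1e-12
  th1 <- msp_params(0.1, 100, 1, floorv)
  th2 <- msp_params(0.1, 100, 2, floorv)
  for (tau in c(0.5, 7, 100, 4321, 1e6)) {
    expect_equal(chmsp(tau, th1) - floorv * tau, 0.1 * 100 * log(1 + tau / 100),
                 tolerance = 1e-9)
    expect_equal(chmsp(tau, th2) - floorv * tau, 0.1 * 100 * atan(tau / 100),
                 tolerance = 1e-9)
  }
  expect_identical(chmsp(0, th1), 0)
  expect_error(chmsp(Inf, th1), "finite")
})

test_that("constant-hazard configuration reduces to the exponential distribution", {
  th <- msp_params(1e-12, 100, 1.5, 1e-3)
  expect_equal(chmsp(1000, th), 1, tolerance = 1e-8)
  expect_equal(smsp(1000, th), exp(-1), tolerance = 1e-8)
  x <- c(0, 50, 500, 5000)
  expect_equal(dmsp(x, th), 1e-3 * exp(-1e-3 * x), tolerance = 1e-8)
  expect_equal(msp_mean(th), 1000, tolerance = 1e-6)
})

test_that("survival, density and cumulative hazard are mutually consistent", {
  th <- msp_params(0.1, 100, 1, 1e-12)
  expect_equal(smsp(100, th), 2^-10, tolerance = 1e-8)
  expect_equal(dmsp(100, th), (0.1 / 2 + 1e-12) * 2^-10, tolerance = 1e-8)
  expect_equal(smsp(0, th), 1)
  for (th in random_thetas(20)) {
    # density integrates to 1: quadrature in log time over the bulk plus the
    # exact survival mass beyond a far quantile
    TT <- qmsp(1 - 1e-10, th)
    bulk <- integrate(function(v) dmsp(exp(v), th) * exp(v), -25, log(TT),
                      rel.tol = 1e-9, subdivisions = 1000L)$value
    mass <- pmsp(exp(-25), th) + bulk + smsp(TT, th)
    expect_equal(mass, 1, tolerance = 1e-6)
    # cumulative hazard increases
    g <- 10^seq(-2, 6, length.out = 50)
    expect_true(all(diff(chmsp(g, th)) > 0))
  }
})

test_that("survival matches a trapezoid-rule oracle across scales", {
  for (th in random_thetas(6, seed = 7)) {
    for (tau in c(1e-2, 3.7, 512, 1e5)) {
      expect_equal(smsp(tau, th), exp(-trapezoid_cumhaz(tau, th)),
                   tolerance = 1e-6)
    }
  }
})

test_that("density agrees with the numerical derivative of survival", {
  th <- msp_params(0.02, 30, 1.45, 1e-4)
  for (tau in c(1, 20, 300, 5000)) {
    h <- tau * 1e-6
    num <- -(smsp(tau + h, th) - smsp(tau - h, th)) / (2 * h)
    expect_equal(dmsp(tau, th), num, tolerance = 1e-4)
  }
})

test_that("mean interevent time matches brute-force quadrature and decreases in lambda_inf", {
  th <- msp_params(0.1, 100, 1, 1e-12)
  # fixed-grid Riemann sum of the survival function
  g <- exp(seq(log(1e-6), log(1e14), length.out = 400001))
  riemann <- sum(diff(c(0, g)) * smsp(g, th))
  expect_equal(msp_mean(th), riemann, tolerance = 1e-4)
  means <- vapply(c(1e-4, 1e-3, 1e-2), function(li)
    msp_mean(msp_params(0.1, 100, 1.5, li)), 1)
  expect_true(all(diff(means) < 0))
})

test_that("quantile function inverts the CDF", {
  th <- msp_params(0.02, 30, 1.45, 1e-4)
  p <- c(1e-4, 0.1, 0.5, 0.9, 0.9999)
  expect_equal(pmsp(qmsp(p, th), th), p, tolerance = 1e-9)
  expect_identical(qmsp(0, th), 0)
  expect_identical(qmsp(1, th), Inf)
})
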