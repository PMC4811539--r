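# Independent oracles used across the suite.  These deliberately avoid the
# package's quadrature and inversion code paths.

# Trapezoid-rule cumulative hazard on a dense log grid.
trapezoid_cumhaz <- function(tau, theta, n_grid = 200001) {
  g <- c(0, exp(seq(log(tau * 1e-10), log(tau), length.out = n_grid)))
  h <- hmsp(g, theta)
  sum(diff(g) * (h[-1] + h[-length(g)]) / 2)
}

# Brute-force O(n^2)-style KS statistic: evaluate both ECDF steps at every
# order statistic by explicit counting.
ks_bruteforce <- function(x, cdf) {
  n <- length(x)
  d <- 0
  for (xi in x) {
    Fh <- cdf(xi)
    ec_at <- sum(x <= xi) / n
    ec_below <- sum(x < xi) / n
    d <- max(d, abs(ec_at - Fh), abs(ec_below - Fh))
  }
  d
}

# Cramer-von Mises statistic by direct quadrature of n * int (F_n - F)^2 dF
# over the probability scale: piecewise polynomial, integrated exactly on
# each interval between consecutive order-statistic probabilities.
cvm_quadrature <- function(x, cdf) {
  n <- length(x)
  u <- sort(cdf(sort(x)))
  knots <- c(0, u, 1)
  tot <- 0
  for (i in seq_len(n + 1)) {
    a <- knots[i]; b <- knots[i + 1]
    e <- (i - 1) / n                     # ECDF value on (a, b)
    # int_a^b (e - t)^2 dt
    tot <- tot + ((e - a)^3 - (e - b)^3) / 3
  }
  n * tot
}

# A reproducible stream of random valid parameter sets spanning the
# realistic ranges.
random_thetas <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    msp_params(10^runif(1, -3, -1), 10^runif(1, 0.5, 3),
               runif(1, 0.4, 3), 10^runif(1, -5, -3))
  })
}
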