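# Baseline waiting-time families: exponential (Poisson process), Pareto with
# a lower cutoff x_m, Weibull and log-normal, plus the power-law-hazard
# special cases of the survival framework.  Exponential, Weibull and
# log-normal go through the stats d/p/q/r functions; the Pareto is supplied
# here (no base-R equivalent).

#' Pareto (power-law) distribution with lower cutoff
#'
#' Density, distribution function, quantile function and random generation
#' for the Pareto distribution with density
#' \eqn{P(\tau) = (a-1)\, x_m^{a-1}\, \tau^{-a}} on \eqn{[x_m, \infty)},
#' the conventional model for power-law interevent tails: data below the
#' cutoff \eqn{x_m} are outside the support (density 0).
#'
#' @param x,q vector of durations.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param xm lower cutoff (> 0), seconds.
#' @param exponent tail exponent \eqn{a > 1} (the density exponent, so the
#'   complementary CDF decays like \eqn{\tau^{-(a-1)}}).
#' @param log,log.p,lower.tail as in the stats distribution functions.
#' @return Numeric vector.
#' @examples
#' dpareto(1, xm = 1, exponent = 2.4)   # 1.4 at the cutoff
#' @name pareto
NULL

#' @rdname pareto
#' @export
dpareto <- function(x, xm, exponent, log = FALSE) {
  stopifnot(xm > 0, exponent > 1)
  ld <- ifelse(x >= xm,
               log(exponent - 1) + (exponent - 1) * log(xm) - exponent * log(pmax(x, xm)),
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname pareto
#' @export
ppareto <- function(q, xm, exponent, lower.tail = TRUE, log.p = FALSE) {
  stopifnot(xm > 0, exponent > 1)
  s <- ifelse(q <= xm, 1, exp((exponent - 1) * (log(xm) - log(pmax(q, xm)))))
  p <- if (lower.tail) 1 - s else s
  if (log.p) log(p) else p
}

#' @rdname pareto
#' @export
qpareto <- function(p, xm, exponent) {
  stopifnot(xm > 0, exponent > 1, all(p >= 0 & p <= 1))
  xm * (1 - p)^(-1 / (exponent - 1))
}

#' @rdname pareto
#' @export
rpareto <- function(n, xm, exponent) qpareto(stats::runif(n), xm, exponent)

#' Maximum-likelihood fit of a baseline waiting-time family
#'
#' Fits one of the four comparison families to an interevent series:
#' exponential (closed form, rate \eqn{1/\bar\tau}), log-normal (closed-form
#' moments of \eqn{\log\tau}), Weibull (one-dimensional root solve of the
#' profile-likelihood shape equation), or Pareto (closed-form Hill estimator
#' of the tail exponent conditional on the cutoff \code{xm}).
#'
#' Zero durations lie outside the support of the log-normal and Pareto
#' families; they are dropped for those fits and counted in
#' \code{n_dropped}.  For the Pareto, observations below \code{xm} are also
#' dropped (cropped) and counted.
#'
#' @param x numeric vector of interevent times (seconds), \eqn{\ge 0},
#'   length \eqn{\ge 3}.
#' @param family one of \code{"exponential"}, \code{"pareto"},
#'   \code{"weibull"}, \code{"lognormal"}.
#' @param xm Pareto lower cutoff; default is the smallest positive duration
#'   (no cropping beyond zeros).
#' @return An object of class \code{"baseline_fit"}: a list with
#'   \code{family}, \code{params} (named numeric), \code{logLik}, \code{n}
#'   (observations used), \code{n_dropped}, and the used data in
#'   \code{data}.
#' @examples
#' fit_baseline(c(1000, 3000), "exponential")$params   # rate = 1/2000
#' fit_baseline(c(1, exp(1), exp(2)), "pareto", xm = 1)$params  # exponent 2
#' @seealso [pareto_tune_xm()], [gof_ks()]
#' @export
fit_baseline <- function(x, family = c("exponential", "pareto", "weibull", "lognormal"),
                         xm = NULL) {
  family <- match.arg(family)
  .check_tau(x)
  n_in <- length(x)
  if (family %in% c("pareto", "lognormal")) {
    x_use <- x[x > 0]
  } else {
    x_use <- x
  }
  dropped <- n_in - length(x_use)
  if (family == "pareto") {
    if (is.null(xm)) xm <- min(x_use)
    below <- x_use < xm
    dropped <- dropped + sum(below)
    x_use <- x_use[!below]
  }
  if (length(x_use) < 2)
    stop("too few usable observations for family '", family, "'", call. = FALSE)
  params <- switch(family,
    exponential = c(rate = 1 / mean(x_use)),
    lognormal = {
      lx <- log(x_use)
      if (stats::sd(lx) == 0)
        stop("degenerate fit: all durations identical", call. = FALSE)
      c(meanlog = mean(lx), sdlog = sqrt(mean((lx - mean(lx))^2)))
    },
    weibull = {
      if (stats::sd(x_use) == 0)
        stop("degenerate fit: all durations identical", call. = FALSE)
      .fit_weibull(x_use)
    },
    pareto = c(xm = xm, exponent = 1 + length(x_use) / sum(log(x_use / xm))))
  ll <- switch(family,
    exponential = sum(stats::dexp(x_use, params[["rate"]], log = TRUE)),
    lognormal = sum(stats::dlnorm(x_use, params[["meanlog"]], params[["sdlog"]], log = TRUE)),
    weibull = sum(stats::dweibull(x_use, params[["shape"]], params[["scale"]], log = TRUE)),
    pareto = sum(dpareto(x_use, params[["xm"]], params[["exponent"]], log = TRUE)))
  structure(list(family = family, params = params, logLik = ll,
                 n = length(x_use), n_dropped = dropped, data = x_use),
            class = "baseline_fit")
}

# Profile-likelihood MLE for the Weibull: solve the standard shape equation
#   sum(x^k log x)/sum(x^k) - 1/k - mean(log x) = 0
# on the positive part of the data, then scale in closed form.  Zeros are
# admitted in the data (they contribute zero density mass only for shape<1;
# the classical MLE profile uses positive observations).
.fit_weibull <- function(x) {
  xp <- x[x > 0]
  lx <- log(xp)
  mlx <- mean(lx)
  g <- function(k) {
    xk <- exp(k * (lx - max(lx)))          # scaled to avoid overflow
    sum(xk * lx) / sum(xk) - 1 / k - mlx
  }
  klo <- 0.01; khi <- 1
  while (g(khi) < 0 && khi < 100) khi <- khi * 2
  k <- stats::uniroot(g, c(klo, khi), tol = 1e-10)$root
  scale <- mean(xp^k)^(1 / k)
  c(shape = k, scale = scale)
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("Baseline fit: %s (n = %d used, %d dropped), log-likelihood = %.3f\n",
              x$family, x$n, x$n_dropped, x$logLik))
  print(round(x$params, 6))
  invisible(x)
}

#' @export
coef.baseline_fit <- function(object, ...) object$params

#' @export
logLik.baseline_fit <- function(object, ...) {
  df <- if (object$family == "exponential") 1 else 2
  structure(object$logLik, df = df, nobs = object$n, class = "logLik")
}

#' @export
simulate.baseline_fit <- function(object, nsim = 1, seed = NULL, n = object$n, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$params
  draw <- switch(object$family,
    exponential = function() stats::rexp(n, p[["rate"]]),
    lognormal = function() stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
    weibull = function() stats::rweibull(n, p[["shape"]], p[["scale"]]),
    pareto = function() rpareto(n, p[["xm"]], p[["exponent"]]))
  replicate(nsim, draw(), simplify = FALSE)
}

# CDF closure of any fitted model (multiscale or baseline) -- the common
# currency of the goodness-of-fit layer.
#' Cumulative distribution function of a fitted model
#'
#' Returns the fitted CDF as a function of duration, for use with the
#' goodness-of-fit tests.
#'
#' @param object an \code{"msp_fit"} or \code{"baseline_fit"}.
#' @return A function \code{F(q)}.
#' @export
dist_cdf <- function(object) UseMethod("dist_cdf")

#' @export
dist_cdf.msp_fit <- function(object) {
  theta <- object$params
  function(q) pmsp(q, theta)
}

#' @export
dist_cdf.baseline_fit <- function(object) {
  p <- object$params
  switch(object$family,
    exponential = function(q) stats::pexp(q, p[["rate"]]),
    lognormal = function(q) stats::plnorm(q, p[["meanlog"]], p[["sdlog"]]),
    weibull = function(q) stats::pweibull(q, p[["shape"]], p[["scale"]]),
    pareto = function(q) ppareto(q, p[["xm"]], p[["exponent"]]))
}

#' Quantile function of a fitted model
#' @param object an \code{"msp_fit"} or \code{"baseline_fit"}.
#' @return A function \code{Q(p)}.
#' @export
dist_quantile <- function(object) UseMethod("dist_quantile")

#' @export
dist_quantile.msp_fit <- function(object) {
  theta <- object$params
  function(p) qmsp(p, theta)
}

#' @export
dist_quantile.baseline_fit <- function(object) {
  p0 <- object$params
  switch(object$family,
    exponential = function(p) stats::qexp(p, p0[["rate"]]),
    lognormal = function(p) stats::qlnorm(p, p0[["meanlog"]], p0[["sdlog"]]),
    weibull = function(p) stats::qweibull(p, p0[["shape"]], p0[["scale"]]),
    pareto = function(p) qpareto(p, p0[["xm"]], p0[["exponent"]]))
}

# number of estimated parameters, for chi-square degrees of freedom
n_fitted_params <- function(object) UseMethod("n_fitted_params")
n_fitted_params.msp_fit <- function(object) 4L
n_fitted_params.baseline_fit <- function(object)
  if (object$family == "exponential") 1L else 2L

#' Tune the Pareto lower cutoff by minimising the KS statistic
#'
#' Scans candidate cutoffs \eqn{x_m} over the order statistics of the series
#' (subsampled to at most \code{max_candidates}), fits the Pareto tail
#' exponent above each candidate by the Hill estimator, computes the KS
#' statistic between the tail data and the fitted Pareto, and returns the
#' cutoff minimising the statistic — the standard convention for power-law
#' fitting with an estimated lower bound.
#'
#' @param x numeric vector of interevent times, length \eqn{\ge 10}.
#' @param max_candidates cap on the number of candidate cutoffs scanned.
#' @param min_tail candidates leaving fewer than this many tail points are
#'   skipped.
#' @return A list with \code{xm}, \code{fit} (the \code{"baseline_fit"} at
#'   the chosen cutoff), \code{cropped_fraction} (fraction of the data
#'   strictly below \code{xm}), \code{ks_statistic}, and the scanned
#'   \code{profile} (data frame of candidate \code{xm}, \code{ks},
#'   \code{cropped_fraction}).
#' @examples
#' set.seed(1)
#' pareto_tune_xm(rpareto(500, 10, 2.5))$xm
#' @export
pareto_tune_xm <- function(x, max_candidates = 200, min_tail = 5) {
  x <- x[x > 0]
  n <- length(x)
  if (n < 10) stop("need at least 10 positive durations", call. = FALSE)
  xs <- sort(x)
  cand <- unique(xs[unique(pmax(1L, round(seq(1, n - min_tail + 1, length.out = max_candidates))))])
  rows <- lapply(cand, function(xm) {
    tail_x <- xs[xs >= xm]
    if (length(tail_x) < min_tail) return(NULL)
    fit <- fit_baseline(tail_x, "pareto", xm = xm)
    D <- ks_stat(tail_x, dist_cdf(fit))
    data.frame(xm = xm, ks = D, cropped_fraction = mean(x < xm))
  })
  profile <- do.call(rbind, rows)
  if (is.null(profile) || !nrow(profile))
    stop("no candidate cutoff leaves enough tail data", call. = FALSE)
  best <- which.min(profile$ks)
  xm <- profile$xm[best]
  list(xm = xm,
       fit = fit_baseline(x[x >= xm], "pareto", xm = xm),
       cropped_fraction = profile$cropped_fraction[best],
       ks_statistic = profile$ks[best],
       profile = profile)
}

#' Waiting-time density induced by a power-law hazard
#'
#' The survival framework's closed special cases: a hazard
#' \eqn{\lambda(\tau) = \gamma / \tau^{\alpha_h}} measured from a lower
#' cutoff \eqn{\tau_{\min} > 0} (the pure \eqn{1/\tau} hazard has a divergent
#' cumulative hazard at 0, so the cutoff is explicit).  For
#' \eqn{\alpha_h = 1} the induced waiting-time density is exactly Pareto
#' with exponent \eqn{1 + \gamma}; for \eqn{\alpha_h < 1} it is exactly
#' Weibull with shape \eqn{1 - \alpha_h}.
#'
#' @param x durations \eqn{\ge \tau_{\min}}.
#' @param gamma hazard coefficient (> 0).
#' @param alpha_h hazard exponent in \eqn{(0, 1]}.
#' @param tau_min lower cutoff (> 0) from which survival is measured.
#' @return Density values (per second); zero below \code{tau_min}.
#' @examples
#' dpowhaz(10, gamma = 1.4, alpha_h = 1, tau_min = 1)  # 1.4 * 10^-2.4
#' @export
dpowhaz <- function(x, gamma, alpha_h = 1, tau_min) {
  stopifnot(gamma > 0, alpha_h > 0, alpha_h <= 1)
  if (!is.numeric(tau_min) || tau_min <= 0)
    stop("tau_min must be strictly positive", call. = FALSE)
  out <- numeric(length(x))
  ok <- x >= tau_min
  xo <- x[ok]
  haz <- gamma / xo^alpha_h
  cumhaz <- if (alpha_h == 1) gamma * (log(xo) - log(tau_min))
            else gamma * (xo^(1 - alpha_h) - tau_min^(1 - alpha_h)) / (1 - alpha_h)
  out[ok] <- haz * exp(-cumhaz)
  out
}
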