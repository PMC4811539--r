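# Maximum-likelihood fitting of the multiscale hazard model.
#
# The log-likelihood of an interevent series T = {tau_1..tau_n} is
#   lnL(theta) = sum_i [ log lambda(tau_i) - Lambda(tau_i) ].
# Fitting is done in log-parameter space (the four parameters are positive
# and span orders of magnitude) with L-BFGS-B inside a generous box, using
# multiple jittered starts.  The expensive piece of each objective
# evaluation, the cumulative hazard at every observation, reuses a fixed
# quadrature skeleton precomputed once per series: the panel knots live in
# data space and do not move with the parameters, so each evaluation is a
# single vectorised pass over precomputed node positions.

# Build a closure lnL(log_theta) for one series, with duplicated durations
# collapsed to unique values with multiplicities.
.make_loglik <- function(tau) {
  ut <- sort(unique(tau))
  w <- as.numeric(tabulate(match(tau, ut)))
  n <- length(tau)
  sum_wt <- sum(w * ut)
  pos <- ut > 0
  up <- ut[pos]
  wp <- w[pos]
  w0 <- if (any(!pos)) w[!pos] else 0   # multiplicity of tau = 0
  if (length(up)) {
    tmax <- max(up)
    lo <- max(min(up) * 1e-8, tmax * 1e-18)
    step <- 1 / .panels_per_decade
    ndec <- ceiling((log10(tmax) - log10(lo)) / step) + 1L
    knots <- c(0, lo * 10^(step * (0:ndec)))
    a <- knots[-length(knots)]
    b <- knots[-1]
    nodes_k <- rep((a + b) / 2, each = 15) + rep((b - a) / 2, each = 15) * .gl15_x
    wts_k <- rep((b - a) / 2, each = 15) * .gl15_w
    idx <- findInterval(up, knots)
    a2 <- knots[idx]
    nodes_p <- rep((a2 + up) / 2, each = 15) + rep((up - a2) / 2, each = 15) * .gl15_x
    wts_p <- rep((up - a2) / 2, each = 15) * .gl15_w
    log_nodes_k <- log(nodes_k)
    log_nodes_p <- log(nodes_p)
    log_up <- log(up)
    P <- length(a)
    m <- length(up)
  }
  function(lt) {
    lt <- unname(lt)
    lambda0 <- exp(lt[1]); log_t0 <- lt[2]; alpha <- exp(lt[3]); linf <- exp(lt[4])
    if (!length(up)) return(n * log(lambda0 + linf))
    fk <- 1 / (1 + exp(alpha * (log_nodes_k - log_t0)))
    cumk <- c(0, cumsum(.colSums(fk * wts_k, 15, P)))
    fp <- 1 / (1 + exp(alpha * (log_nodes_p - log_t0)))
    I <- cumk[idx] + .colSums(fp * wts_p, 15, m)        # int_0^tau_i f dt
    fdat <- 1 / (1 + exp(alpha * (log_up - log_t0)))
    ll <- sum(wp * log(lambda0 * fdat + linf)) - linf * sum_wt - lambda0 * sum(wp * I)
    if (w0 > 0) ll <- ll + w0 * log(lambda0 + linf)
    ll
  }
}

#' Log-likelihood of an interevent series under the multiscale model
#'
#' Computes \eqn{\sum_i [\log\lambda(\tau_i|\theta) - \Lambda(\tau_i|\theta)]},
#' which equals \eqn{\sum_i \log P(\tau_i|\theta)}.  Finite for all valid
#' inputs, including zero waiting times (the density at 0 is
#' \eqn{\lambda_0+\lambda_\infty}).
#'
#' @param x numeric vector of interevent times (seconds), \eqn{\ge 0}.
#' @param theta an [msp_params()] object.
#' @return A single number.
#' @export
msp_loglik <- function(x, theta) {
  theta <- as_msp_params(theta)
  .check_tau(x)
  if (!length(x)) stop("empty series", call. = FALSE)
  .make_loglik(x)(log(unclass(theta)))
}

# Default initialisation: tie lambda0 to the short-time rate, lambda_inf to
# the overall mean rate, t0 to the median, alpha to a typical burst exponent.
.msp_init <- function(x) {
  xp <- x[x > 0]
  res <- if (length(xp)) min(xp) else 1
  q25 <- stats::quantile(x, 0.25, names = FALSE)
  short <- x[x <= q25]
  lambda0 <- 1 / (mean(short) + res)
  t0 <- max(stats::median(x), res)
  lambda_inf <- 1 / max(mean(x), res)
  c(log(lambda0), log(t0), log(1.5), log(lambda_inf))
}

#' Fit the multiscale interevent-time model by maximum likelihood
#'
#' Estimates the four hazard parameters \eqn{\{\lambda_0, t_0, \alpha,
#' \lambda_\infty\}} for one individual's interevent series by maximising the
#' log-likelihood with multi-start quasi-Newton optimisation (L-BFGS-B in
#' log-parameter space).  The first start uses moment-style heuristics (the
#' short-time rate for \eqn{\lambda_0}, the median for \eqn{t_0}, the inverse
#' mean for \eqn{\lambda_\infty}); the remaining starts jitter each
#' log-parameter by Normal(0, 0.5^2) draws controlled by \code{seed}.
#'
#' @param x numeric vector of interevent times (seconds), \eqn{\ge 0}.
#'   Series shorter than 20 observations are fitted with a warning recorded
#'   in the result.
#' @param n_starts number of optimiser starts (\eqn{\ge 1}).
#' @param seed integer seed for the start jitter; \code{NULL} leaves the RNG
#'   state alone.
#' @param max_iter maximum optimiser iterations per start.
#' @param lower,upper bounds on \eqn{(\log\lambda_0, \log t_0, \log\alpha,
#'   \log\lambda_\infty)}.  Defaults keep rates in \eqn{[10^{-12}, 10^{3}]},
#'   \eqn{t_0} within four decades of the observed range and
#'   \eqn{\alpha \in [0.05, 20]}.
#' @return An object of class \code{"msp_fit"} with components
#'   \code{params} (an [msp_params()]), \code{logLik}, \code{converged},
#'   \code{n_starts}, \code{start_best}, \code{n}, \code{warnings}, and the
#'   original data in \code{data}.
#' @examples
#' theta <- msp_params(0.02, 30, 1.45, 1e-4)
#' set.seed(2)
#' fit <- msp_fit(rmsp(2000, theta), seed = 2)
#' coef(fit)
#' @seealso [msp_loglik()], [gof_ks()], [fit_baseline()]
#' @export
msp_fit <- function(x, n_starts = 5, seed = NULL, max_iter = 300,
                    lower = NULL, upper = NULL) {
  .check_tau(x)
  n <- length(x)
  warns <- character()
  if (n < 20) warns <- c(warns, "fewer than 20 observations; estimates will be unstable")
  xp <- x[x > 0]
  if (!length(xp)) stop("all interevent times are zero; model not identifiable", call. = FALSE)
  if (is.null(lower))
    lower <- log(c(1e-12, min(xp) * 1e-4, 0.05, 1e-12))
  if (is.null(upper))
    upper <- log(c(1e3, max(xp) * 1e4, 20, 1e3))
  nll_env <- .make_loglik(x)
  negll <- function(lt) -nll_env(lt)
  init <- pmin(pmax(.msp_init(x), lower), upper)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  starts <- matrix(rep(init, n_starts), ncol = n_starts)
  if (n_starts > 1)
    starts[, -1] <- starts[, -1] + stats::rnorm(4 * (n_starts - 1), 0, 0.5)
  if (n_starts > 1) {
    # deterministic start at the nested exponential corner (lambda0 at its
    # floor, lambda_inf at the inverse mean) so the fit never falls below
    # the homogeneous-Poisson special case
    starts[, 2] <- c(lower[1], init[2], log(1.5), log(1 / max(mean(x), 1e-12)))
  }
  starts <- pmin(pmax(starts, lower), upper)
  best <- NULL
  best_ll <- -Inf
  best_i <- NA_integer_
  any_conv <- FALSE
  for (i in seq_len(n_starts)) {
    fit_i <- tryCatch(
      stats::optim(starts[, i], negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = max_iter, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(fit_i)) next
    if (fit_i$convergence == 0) any_conv <- TRUE
    if (-fit_i$value > best_ll) {
      best_ll <- -fit_i$value
      best <- fit_i
      best_i <- i
    }
  }
  if (is.null(best)) stop("all optimiser starts failed", call. = FALSE)
  th <- exp(best$par)
  theta <- msp_params(th[1], th[2], th[3], th[4])
  if (theta[["lambda_inf"]] >= theta[["lambda0"]])
    warns <- c(warns, "lambda_inf >= lambda0: fitted tail rate is not small relative to the short-time rate")
  if (any(abs(best$par - lower) < 1e-8))
    warns <- c(warns, "one or more parameters at the lower bound")
  structure(list(params = theta, logLik = best_ll,
                 converged = best$convergence == 0 || any_conv,
                 n_starts = n_starts, start_best = best_i, n = n,
                 warnings = warns, data = x),
            class = "msp_fit")
}

#' @export
print.msp_fit <- function(x, ...) {
  cat("Multiscale interevent-time model fit\n")
  cat(sprintf("  n = %d observations, log-likelihood = %.3f (%d starts, best = #%d)\n",
              x$n, x$logLik, x$n_starts, x$start_best))
  print(x$params)
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.msp_fit <- function(object, ...) unclass(object$params)[1:4]

#' @export
logLik.msp_fit <- function(object, ...) {
  structure(object$logLik, df = 4, nobs = object$n, class = "logLik")
}

#' @export
summary.msp_fit <- function(object, ...) {
  ks <- gof_ks(object$data, object)
  structure(list(fit = object, mean_interevent = msp_mean(object$params), ks = ks),
            class = "summary.msp_fit")
}

#' @export
print.summary.msp_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  implied mean interevent time: %.1f s\n", x$mean_interevent))
  cat(sprintf("  KS goodness of fit: D = %.4f, p = %.4f\n", x$ks$statistic, x$ks$p_value))
  invisible(x)
}

#' Predicted distribution functions from a fitted multiscale model
#'
#' @param object an \code{"msp_fit"}.
#' @param newdata waiting times (for types \code{"density"},
#'   \code{"survival"}, \code{"hazard"}, \code{"cdf"}) or probabilities (for
#'   \code{"quantile"}); defaults to the fitted data.
#' @param type which function of the fitted distribution to evaluate.
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.msp_fit <- function(object, newdata = NULL,
                            type = c("density", "survival", "hazard", "cdf", "quantile"),
                            ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    newdata <- if (type == "quantile") stats::ppoints(object$n) else object$data
  switch(type,
         density = dmsp(newdata, object$params),
         survival = smsp(newdata, object$params),
         hazard = hmsp(newdata, object$params),
         cdf = pmsp(newdata, object$params),
         quantile = qmsp(newdata, object$params))
}

#' @export
simulate.msp_fit <- function(object, nsim = 1, seed = NULL, n = object$n, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, rmsp(n, object$params), simplify = FALSE)
}

#' Cox--Snell residuals of a fitted multiscale model
#'
#' The cumulative hazard evaluated at the observations,
#' \eqn{\Lambda(\tau_i|\hat\theta)}, which is a standard-exponential sample
#' when the model is correct.
#'
#' @param object an \code{"msp_fit"}.
#' @param ... unused.
#' @return Numeric vector of length \code{object$n}.
#' @export
residuals.msp_fit <- function(object, ...) chmsp(object$data, object$params)

#' Diagnostic plot of a fitted multiscale model
#'
#' Draws the log-binned empirical density of the data with the fitted density
#' overlaid on log-log axes, and (optionally) the empirical vs fitted
#' survival curve.
#'
#' @param x an \code{"msp_fit"}.
#' @param which \code{"density"}, \code{"survival"} or both.
#' @param bins_per_decade histogram resolution for the empirical density.
#' @param ... passed to \code{plot}.
#' @export
plot.msp_fit <- function(x, which = c("density", "survival"),
                         bins_per_decade = 10, ...) {
  which <- match.arg(which, several.ok = TRUE)
  tau <- x$data[x$data > 0]
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if ("density" %in% which) {
    eb <- empirical_density_logbins(tau, bins_per_decade)
    grid <- 10^seq(log10(min(tau)), log10(max(tau)), length.out = 200)
    graphics::plot(eb$tau, eb$density, log = "xy",
                   xlab = "interevent time (s)", ylab = "density",
                   main = "density", ...)
    graphics::lines(grid, dmsp(grid, x$params), col = 2, lwd = 2)
  }
  if ("survival" %in% which) {
    ts <- sort(tau)
    grid <- 10^seq(log10(min(tau)), log10(max(tau)), length.out = 200)
    graphics::plot(ts, 1 - seq_along(ts) / length(ts), log = "x", type = "s",
                   xlab = "interevent time (s)", ylab = "survival",
                   main = "survival", ...)
    graphics::lines(grid, smsp(grid, x$params), col = 2, lwd = 2)
  }
  invisible(x)
}

#' Log-binned empirical density
#'
#' Histogram of positive durations on logarithmically spaced bins,
#' normalised to a probability density; the standard estimator for
#' heavy-tailed interevent data.
#'
#' @param x positive durations.
#' @param bins_per_decade number of bins per factor of 10.
#' @return A data frame with columns \code{tau} (geometric bin centre),
#'   \code{density} and \code{count}; empty bins are dropped.
#' @export
empirical_density_logbins <- function(x, bins_per_decade = 20) {
  x <- x[x > 0]
  lo <- floor(log10(min(x)) * bins_per_decade) / bins_per_decade
  hi <- ceiling(log10(max(x)) * bins_per_decade) / bins_per_decade
  brk <- 10^seq(lo, hi + 1e-9, by = 1 / bins_per_decade)
  cnt <- graphics::hist(x, breaks = brk, plot = FALSE)$counts
  widths <- diff(brk)
  centre <- sqrt(brk[-length(brk)] * brk[-1])
  keep <- cnt > 0
  data.frame(tau = centre[keep],
             density = cnt[keep] / (length(x) * widths[keep]),
             count = cnt[keep])
}
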