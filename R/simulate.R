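# Cohort simulation: per-individual hazard parameters drawn from population
# distributions (log-normal rates and timescale, skew-normal burst
# exponent), then exact renewal sampling by cumulative-hazard inversion.
# This is also the package's fixture generator: the real chat/email cohorts
# it emulates are proprietary, so synthetic cohorts stand in for them.

#' Population configuration for cohort simulation
#'
#' Describes the distributions from which each simulated individual's hazard
#' parameters are drawn.  The defaults emulate the population heterogeneity
#' observed in large messaging cohorts: \eqn{\lambda_0} and \eqn{t_0}
#' log-normal (with \eqn{t_0} modal near 100 s on the log10 scale used
#' here), \eqn{\lambda_\infty} log-normal with a lower truncation (slow
#' responders are under-sampled in real cohorts), and \eqn{\alpha}
#' skew-normal with mean near 1.45, positively skewed, truncated away from
#' zero.
#'
#' @param n_users number of individuals.
#' @param lambda0_log10_mean,lambda0_log10_sd Normal parameters of
#'   \eqn{\log_{10}\lambda_0}.
#' @param t0_log10_mean,t0_log10_sd Normal parameters of \eqn{\log_{10}t_0}.
#' @param lambda_inf_log10_mean,lambda_inf_log10_sd Normal parameters of
#'   \eqn{\log_{10}\lambda_\infty}.
#' @param lambda_inf_min lower truncation for \eqn{\lambda_\infty}
#'   (rejection sampling).
#' @param alpha_mean,alpha_sd mean and standard deviation of the
#'   skew-normal for \eqn{\alpha} (before truncation).
#' @param alpha_slant skew-normal slant parameter (positive = right skew).
#' @param alpha_min lower truncation for \eqn{\alpha}.
#' @param events_range integer range (inclusive) of events per individual,
#'   drawn uniformly.
#' @param seed master seed; per-individual sub-seeds are derived from it
#'   deterministically.
#' @return An object of class \code{"population_config"} (a validated
#'   list).
#' @seealso [sample_population()]
#' @export
population_config <- function(n_users = 200,
                              lambda0_log10_mean = -1.7, lambda0_log10_sd = 0.3,
                              t0_log10_mean = 1.7, t0_log10_sd = 0.3,
                              lambda_inf_log10_mean = -4, lambda_inf_log10_sd = 0.3,
                              lambda_inf_min = 1e-6,
                              alpha_mean = 1.45, alpha_sd = 0.3,
                              alpha_slant = 4, alpha_min = 0.2,
                              events_range = c(200L, 1000L),
                              seed = 1) {
  stopifnot(n_users >= 1, lambda0_log10_sd > 0, t0_log10_sd > 0,
            lambda_inf_log10_sd > 0, lambda_inf_min > 0,
            alpha_sd > 0, alpha_min > 0,
            length(events_range) == 2, events_range[1] >= 1,
            events_range[2] >= events_range[1])
  structure(list(n_users = as.integer(n_users),
                 lambda0_log10_mean = lambda0_log10_mean,
                 lambda0_log10_sd = lambda0_log10_sd,
                 t0_log10_mean = t0_log10_mean, t0_log10_sd = t0_log10_sd,
                 lambda_inf_log10_mean = lambda_inf_log10_mean,
                 lambda_inf_log10_sd = lambda_inf_log10_sd,
                 lambda_inf_min = lambda_inf_min,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 alpha_slant = alpha_slant, alpha_min = alpha_min,
                 events_range = as.integer(events_range),
                 seed = as.integer(seed)),
            class = "population_config")
}

#' @export
print.population_config <- function(x, ...) {
  cat("Population configuration:\n")
  cat(sprintf("  %d users, %d-%d events each, master seed %d\n",
              x$n_users, x$events_range[1], x$events_range[2], x$seed))
  cat(sprintf("  log10 lambda0 ~ N(%.2f, %.2f); log10 t0 ~ N(%.2f, %.2f)\n",
              x$lambda0_log10_mean, x$lambda0_log10_sd,
              x$t0_log10_mean, x$t0_log10_sd))
  cat(sprintf("  log10 lambda_inf ~ N(%.2f, %.2f), truncated >= %g\n",
              x$lambda_inf_log10_mean, x$lambda_inf_log10_sd, x$lambda_inf_min))
  cat(sprintf("  alpha ~ skew-normal(mean %.2f, sd %.2f, slant %.1f), truncated > %g\n",
              x$alpha_mean, x$alpha_sd, x$alpha_slant, x$alpha_min))
  invisible(x)
}

# Skew-normal draws with a given mean, sd and slant, by the standard
# two-normal construction: z = delta*|u0| + sqrt(1-delta^2)*u1.
.rskewnorm <- function(n, mean, sd, slant) {
  delta <- slant / sqrt(1 + slant^2)
  mz <- delta * sqrt(2 / pi)
  sz <- sqrt(1 - mz^2)
  omega <- sd / sz
  xi <- mean - omega * mz
  u0 <- abs(stats::rnorm(n))
  u1 <- stats::rnorm(n)
  xi + omega * (delta * u0 + sqrt(1 - delta^2) * u1)
}

# Rejection sampling against a lower truncation, with a tries cap.
.draw_truncated <- function(draw1, accept, n, max_tries = 1000L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (tr in seq_len(max_tries)) {
      v <- draw1()
      if (accept(v)) break
      if (tr == max_tries)
        stop("rejection sampling exceeded ", max_tries,
             " tries: truncation too tight for the configured distribution",
             call. = FALSE)
    }
    out[i] <- v
  }
  out
}

#' Simulate a synthetic cohort from the multiscale renewal model
#'
#' Draws one parameter set per individual from the distributions in a
#' [population_config()], then one interevent series per individual by
#' exact cumulative-hazard inversion ([rmsp()]).  Per-individual sub-seeds
#' are derived deterministically from the master seed, so cohorts are fully
#' reproducible and individual series can be regenerated independently.
#'
#' @param config a [population_config()].
#' @return An object of class \code{"msp_cohort"}: a list with
#'   \code{users} (each a list with \code{id}, \code{params} — an
#'   [msp_params()] — and \code{tau}, the interevent series) and
#'   \code{config}.
#' @examples
#' coh <- sample_population(population_config(n_users = 3, events_range = c(50, 80)))
#' length(coh$users)
#' @seealso [rmsp()], [to_event_log()], [evaluate_population()]
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  n <- config$n_users
  lambda0 <- 10^stats::rnorm(n, config$lambda0_log10_mean, config$lambda0_log10_sd)
  t0 <- 10^stats::rnorm(n, config$t0_log10_mean, config$t0_log10_sd)
  lambda_inf <- .draw_truncated(
    function() 10^stats::rnorm(1, config$lambda_inf_log10_mean, config$lambda_inf_log10_sd),
    function(v) v >= config$lambda_inf_min, n)
  alpha <- .draw_truncated(
    function() .rskewnorm(1, config$alpha_mean, config$alpha_sd, config$alpha_slant),
    function(v) v > config$alpha_min, n)
  n_events <- sample(seq(config$events_range[1], config$events_range[2]), n, replace = TRUE)
  users <- lapply(seq_len(n), function(i) {
    theta <- msp_params(lambda0[i], t0[i], alpha[i], lambda_inf[i])
    sub_seed <- as.integer((as.double(config$seed) * 10007 + i) %% 2147483647)
    set.seed(sub_seed)
    list(id = sprintf("u%04d", i), params = theta, tau = rmsp(n_events[i], theta))
  })
  structure(list(users = users, config = config), class = "msp_cohort")
}

#' @export
print.msp_cohort <- function(x, ...) {
  ns <- vapply(x$users, function(u) length(u$tau), 1L)
  cat(sprintf("Synthetic cohort: %d users, %d-%d events per user (seed %d)\n",
              length(x$users), min(ns), max(ns), x$config$seed))
  invisible(x)
}

#' Convert a cohort of interevent series to an event log
#'
#' Cumulative-sums each individual's interevent series from time 0 into
#' event timestamps.  The round trip through
#' [intervals_from_timestamps()] returns the generating durations exactly
#' (up to floating-point addition) when \code{quantize = FALSE}.
#'
#' @param cohort an \code{"msp_cohort"} or a named list of numeric
#'   interevent series.
#' @param quantize if \code{TRUE}, floor timestamps to whole seconds (the
#'   resolution of typical message logs); reconstructed interevent times
#'   then differ from the generating ones by less than 1 s each.
#' @return A data frame with columns \code{id} (character) and \code{time}
#'   (seconds from 0), sorted by id then time.
#' @examples
#' to_event_log(list(u1 = c(10, 15)))   # times 0, 10, 25
#' @export
to_event_log <- function(cohort, quantize = FALSE) {
  series <- .cohort_series(cohort)
  ids <- if (inherits(cohort, "msp_cohort")) vapply(cohort$users, `[[`, "", "id")
         else if (!is.null(names(series))) names(series)
         else sprintf("u%04d", seq_along(series))
  if (!length(series)) stop("empty cohort", call. = FALSE)
  out <- do.call(rbind, lapply(seq_along(series), function(i) {
    times <- cumsum(c(0, series[[i]]))
    if (quantize) times <- floor(times)
    data.frame(id = ids[i], time = times)
  }))
  rownames(out) <- NULL
  out
}
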