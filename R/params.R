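#' Multiscale hazard parameters
#'
#' Construct and validate the four-parameter specification of the multiscale
#' intensity (hazard) function
#' \deqn{\lambda(\tau) = \frac{\lambda_0}{(\tau/t_0)^\alpha + 1} + \lambda_\infty,}
#' which interpolates between a short-time plateau at \eqn{\lambda_0 +
#' \lambda_\infty}, an intermediate power-law ("burst") regime with exponent
#' governed by \eqn{\alpha}, and a constant long-time rate \eqn{\lambda_\infty}
#' that produces an exponential tail in the induced waiting-time distribution.
#'
#' All four parameters must be strictly positive.  Exact zeros are not
#' admitted; limiting cases (e.g. a pure exponential) are represented by
#' pushing the relevant rate to a small floor such as \code{1e-12}, which keeps
#' the log-likelihood finite and the optimisation domain open.  When
#' \code{lambda_inf >= lambda0} the object carries a \code{"diagnostics"}
#' attribute noting that the usual interpretation (a tail rate much smaller
#' than the quick-response rate) does not apply; this is a flag, not an error.
#'
#' @param lambda0 short-timescale activity rate, events per second.
#' @param t0 critical timescale (seconds) at which burstiness sets in.
#' @param alpha dimensionless exponent controlling the heterogeneity of the
#'   burst regime.
#' @param lambda_inf long-timescale activity rate, events per second; sets the
#'   exponential tail and dominates the mean interevent time.
#' @return An object of class \code{"msp_params"}: a named numeric vector of
#'   length four.
#' @examples
#' theta <- msp_params(lambda0 = 0.1, t0 = 100, alpha = 1.5, lambda_inf = 1e-4)
#' hmsp(c(0, 100, 1e9), theta)
#' @seealso [hmsp()], [dmsp()], [msp_fit()], [rmsp()]
#' @export
msp_params <- function(lambda0, t0, alpha, lambda_inf) {
  th <- c(lambda0 = as.numeric(lambda0), t0 = as.numeric(t0),
          alpha = as.numeric(alpha), lambda_inf = as.numeric(lambda_inf))
  if (any(!is.finite(th)))
    stop("all parameters must be finite", call. = FALSE)
  if (any(th <= 0))
    stop("all parameters must be strictly positive (use a small floor, e.g. 1e-12, for limiting cases)",
         call. = FALSE)
  class(th) <- "msp_params"
  if (th[["lambda_inf"]] >= th[["lambda0"]])
    attr(th, "diagnostics") <-
      "lambda_inf >= lambda0: tail rate is not small relative to the quick-response rate"
  th
}

#' @export
print.msp_params <- function(x, digits = 4, ...) {
  cat("Multiscale hazard parameters:\n")
  cat(sprintf("  lambda0    = %.*g  (events/s, short-time rate)\n", digits, x[["lambda0"]]))
  cat(sprintf("  t0         = %.*g  (s, critical timescale)\n", digits, x[["t0"]]))
  cat(sprintf("  alpha      = %.*g  (burst-regime exponent)\n", digits, x[["alpha"]]))
  cat(sprintf("  lambda_inf = %.*g  (events/s, tail rate)\n", digits, x[["lambda_inf"]]))
  if (!is.null(attr(x, "diagnostics")))
    cat("  note:", attr(x, "diagnostics"), "\n")
  invisible(x)
}

# Coerce a length-4 numeric (or msp_params) to validated msp_params.
as_msp_params <- function(theta) {
  if (inherits(theta, "msp_params")) return(theta)
  if (!is.numeric(theta) || length(theta) != 4)
    stop("theta must be an 'msp_params' object or a numeric vector of length 4",
         call. = FALSE)
  if (is.null(names(theta)) || !all(c("lambda0", "t0", "alpha", "lambda_inf") %in% names(theta)))
    names(theta) <- c("lambda0", "t0", "alpha", "lambda_inf")
  msp_params(theta[["lambda0"]], theta[["t0"]], theta[["alpha"]], theta[["lambda_inf"]])
}
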