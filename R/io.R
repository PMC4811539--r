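# Event-log ingestion and results serialization.  Input is delimited text
# with two columns (individual id, event time in seconds), comma or tab
# separated, optional header; times are plain seconds — calendar parsing is
# deliberately out of scope.

#' Read a two-column event log
#'
#' Parses a delimited text file of (individual id, event time in seconds),
#' comma- or tab-separated, with an optional header.  Malformed lines
#' (wrong field count, non-numeric time) are skipped and counted; times are
#' sorted within each individual, with a notice if any were out of order.
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} (default) auto-detects comma vs
#'   tab from the first data line.
#' @return A data frame with columns \code{id} and \code{time}, sorted by
#'   (id, time), with attribute \code{n_malformed}.
#' @seealso [intervals_from_timestamps()], [to_event_log()]
#' @export
read_event_log <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty event log: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\t", lines[1])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  ok2 <- lengths(parts) == 2L
  id <- vapply(parts[ok2], function(p) trimws(p[1]), "")
  tm <- suppressWarnings(as.numeric(vapply(parts[ok2], function(p) trimws(p[2]), "")))
  # a header line shows up as a non-numeric time in the first record
  num_ok <- is.finite(tm)
  n_malformed <- sum(!ok2) + sum(!num_ok)
  header_like <- !num_ok & seq_along(num_ok) == 1L
  n_malformed <- n_malformed - sum(header_like)   # a header is not malformed
  bad <- which(!num_ok & !header_like)
  if (length(bad))
    message(sprintf("read_event_log: skipped %d malformed line(s), e.g. line %d",
                    length(bad), bad[1]))
  id <- id[num_ok]; tm <- tm[num_ok]
  if (!length(tm)) stop("no valid records in ", path, call. = FALSE)
  unordered <- any(vapply(split(tm, id), is.unsorted, TRUE))
  if (unordered) message("read_event_log: out-of-order timestamps sorted within id")
  o <- order(id, tm)
  out <- data.frame(id = id[o], time = tm[o])
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Interevent series from an event log
#'
#' Per individual, takes consecutive differences of the sorted event times.
#' Individuals with a single event yield an empty series and are excluded
#' (with a count); individuals with \code{n <= min_events} interevent times
#' are flagged inactive but retained.
#'
#' @param log a data frame with columns \code{id} and \code{time} (see
#'   [read_event_log()]).
#' @param zero_policy what to do with zero interevent times (same-second
#'   events): \code{"keep"} (default; the model's likelihood is finite at
#'   0), \code{"drop"}, or \code{"jitter"} (add Uniform(0, resolution)
#'   noise).
#' @param resolution jitter amplitude in seconds.
#' @param min_events activity threshold; series with no more than this many
#'   durations are marked inactive in the \code{active} attribute.
#' @return A named list of numeric interevent series, with attributes
#'   \code{active} (logical per series) and \code{n_excluded}
#'   (single-event individuals).
#' @examples
#' log <- data.frame(id = "u1", time = c(0, 10, 25))
#' intervals_from_timestamps(log)$u1   # 10 15
#' @export
intervals_from_timestamps <- function(log, zero_policy = c("keep", "drop", "jitter"),
                                      resolution = 1, min_events = 100) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(is.data.frame(log), all(c("id", "time") %in% names(log)))
  series <- lapply(split(log$time, factor(log$id, levels = unique(log$id))),
                   function(tt) diff(sort(tt)))
  empty <- vapply(series, length, 1L) == 0L
  if (any(empty))
    message(sprintf("intervals_from_timestamps: excluded %d single-event individual(s)",
                    sum(empty)))
  series <- series[!empty]
  series <- lapply(series, function(tau) {
    switch(zero_policy,
           keep = tau,
           drop = tau[tau > 0],
           jitter = tau + stats::runif(length(tau), 0, resolution) * (tau == 0))
  })
  attr(series, "active") <- vapply(series, length, 1L) > min_events
  attr(series, "n_excluded") <- sum(empty)
  series
}

#' Fit every individual in a cohort and tabulate the results
#'
#' The per-individual analysis pipeline in one call: fit the multiscale
#' model to each series, run the three goodness-of-fit tests, and return
#' one row per successfully fitted individual.
#'
#' @param series a named list of interevent series (see
#'   [intervals_from_timestamps()]) or an \code{"msp_cohort"}.
#' @param min_events only series with more than this many durations are
#'   fitted.
#' @param level significance level for the pass flags.
#' @param seed,n_starts passed to [msp_fit()] (the seed is offset per
#'   individual).
#' @param progress print a line every 25 individuals.
#' @return A data frame with columns \code{id}, \code{n}, \code{lambda0},
#'   \code{t0}, \code{alpha}, \code{lambda_inf}, \code{logLik},
#'   \code{ks_stat}, \code{ks_p}, \code{chisq_stat}, \code{chisq_p},
#'   \code{cvm_stat}, \code{cvm_p}, \code{warnings}; failures are dropped
#'   with a message and counted in the \code{n_failed} attribute.
#' @export
cohort_fit_table <- function(series, min_events = 100, level = 0.05,
                             seed = 1, n_starts = 5, progress = FALSE) {
  if (inherits(series, "msp_cohort")) {
    ids <- vapply(series$users, `[[`, "", "id")
    series <- .cohort_series(series)
    names(series) <- ids
  }
  if (is.null(names(series))) names(series) <- sprintf("u%04d", seq_along(series))
  keep <- vapply(series, length, 1L) > min_events
  series <- series[keep]
  rows <- list()
  n_failed <- 0L
  for (i in seq_along(series)) {
    x <- series[[i]]
    fit <- tryCatch(msp_fit(x, n_starts = n_starts, seed = seed + i),
                    error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    ks <- gof_ks(x, fit, level)
    ch <- tryCatch(gof_chisq(x, fit, level), error = function(e) NULL)
    cv <- gof_cvm(x, fit, level)
    th <- coef(fit)
    rows[[length(rows) + 1L]] <- data.frame(
      id = names(series)[i], n = fit$n,
      lambda0 = th[["lambda0"]], t0 = th[["t0"]],
      alpha = th[["alpha"]], lambda_inf = th[["lambda_inf"]],
      logLik = fit$logLik,
      ks_stat = ks$statistic, ks_p = ks$p_value,
      chisq_stat = if (is.null(ch)) NA_real_ else ch$statistic,
      chisq_p = if (is.null(ch)) NA_real_ else ch$p_value,
      cvm_stat = cv$statistic, cvm_p = cv$p_value,
      warnings = paste(fit$warnings, collapse = "; "))
    if (progress && i %% 25 == 0) message("fitted ", i, " / ", length(series))
  }
  if (n_failed > 0)
    message(sprintf("cohort_fit_table: %d fit failure(s) excluded", n_failed))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}

#' Population summaries of fitted hazard parameters
#'
#' For each of the four hazard parameters across a cohort fit table:
#' mean, median, a histogram-mode estimate, and the histogram itself —
#' log10-spaced bins for the rates and the timescale, linear bins for the
#' burst exponent.
#'
#' @param fit_table output of [cohort_fit_table()] (needs at least 2 rows).
#' @param bins number of histogram bins.
#' @return A list with \code{summary} (data frame: parameter, mean, median,
#'   mode, scale) and \code{histograms} (named list of data frames with
#'   \code{mid}, \code{count}).
#' @export
summarize_population <- function(fit_table, bins = 30) {
  stopifnot(is.data.frame(fit_table), nrow(fit_table) >= 2)
  cols <- c("lambda0", "t0", "alpha", "lambda_inf")
  log_scale <- c(TRUE, TRUE, FALSE, TRUE)
  hists <- list()
  rows <- lapply(seq_along(cols), function(j) {
    v <- fit_table[[cols[j]]]
    vv <- if (log_scale[j]) log10(v) else v
    rng <- range(vv)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    brk <- seq(rng[1], rng[2], length.out = bins + 1)
    h <- graphics::hist(vv, breaks = brk, plot = FALSE, include.lowest = TRUE)
    mode_v <- h$mids[which.max(h$counts)]
    hists[[cols[j]]] <<- data.frame(
      mid = if (log_scale[j]) 10^h$mids else h$mids, count = h$counts)
    data.frame(parameter = cols[j], mean = mean(v), median = stats::median(v),
               mode = if (log_scale[j]) 10^mode_v else mode_v,
               scale = if (log_scale[j]) "log10" else "linear")
  })
  list(summary = do.call(rbind, rows), histograms = hists)
}

#' Write an event log or a results table as delimited text
#'
#' @param x a data frame.
#' @param path output file.
#' @param sep field separator.
#' @export
write_delim_table <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
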