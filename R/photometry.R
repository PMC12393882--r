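# Two-channel fiber photometry preprocessing: first-minute trim,
# triple-exponential bleaching correction, z-scoring, isosbestic QC.

#' Remove the first minute of a photometry trace
#'
#' The first minute after light onset is dominated by fast bleaching
#' artifacts and is discarded. Calling this twice removes two minutes; the
#' operation is deliberately not idempotent.
#'
#' @param trace numeric vector
#' @param fs sampling rate in Hz
#' @param trim_s seconds to remove (default 60)
#' @return the trace with the first `trim_s * fs` samples dropped
#' @export
trim_first_minute <- function(trace, fs, trim_s = 60) {
  n_trim <- as.integer(round(trim_s * fs))
  if (length(trace) <= n_trim)
    stop(sprintf("trace (%d samples) is not longer than the %g s trim",
                 length(trace), trim_s))
  trace[(n_trim + 1L):length(trace)]
}

#' Subtract a triple-exponential bleaching trend
#'
#' Fits c0 + sum_i a_i exp(-t / tau_i) (i = 1..3, a_i >= 0, tau_i > 0) by
#' nonlinear least squares and subtracts the fit. Initial time constants span
#' the bleaching scales (duration/2, duration/10, duration/50) and initial
#' amplitudes split the observed decay range. On non-convergence the model
#' falls back to a double, then single exponential; which model was used is
#' recorded.
#'
#' @param trace numeric vector
#' @param fs sampling rate in Hz
#' @return list with `trace` (detrended), `fit` (fitted trend), `params`
#'   (named coefficients), `model` ("triple", "double", "single" or "mean"),
#'   `rss` (residual sum of squares)
#' @export
detrend_triple_exponential <- function(trace, fs) {
  stopifnot(all(is.finite(trace)), length(trace) >= 100L, fs > 0)
  n <- length(trace)
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  drop0 <- max(trace[seq_len(max(2L, round(n / 100)))]) - mean(trace)
  amp0 <- max(abs(drop0), stats::sd(trace), 1e-6)
  df <- data.frame(y = trace, t = t)
  fit_k <- function(k) {
    taus <- (dur / c(2, 10, 50))[seq_len(k)]
    a0 <- rep(amp0 / k, k)
    frm <- switch(k,
      y ~ c0 + a1 * exp(-t / tau1),
      y ~ c0 + a1 * exp(-t / tau1) + a2 * exp(-t / tau2),
      y ~ c0 + a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + a3 * exp(-t / tau3))
    start <- c(list(c0 = min(trace)),
               stats::setNames(as.list(a0), paste0("a", seq_len(k))),
               stats::setNames(as.list(taus), paste0("tau", seq_len(k))))
    lower <- c(-Inf, rep(0, k), rep(1e-3, k))
    tryCatch(
      minpack.lm::nlsLM(frm, data = df, start = start, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- NULL
  model <- "mean"
  for (k in 3:1) {
    fit <- fit_k(k)
    if (!is.null(fit)) {
      model <- c("single", "double", "triple")[k]
      break
    }
  }
  if (is.null(fit)) {
    trend <- rep(mean(trace), n)
    params <- c(c0 = mean(trace))
  } else {
    trend <- as.numeric(stats::fitted(fit))
    params <- stats::coef(fit)
  }
  resid <- trace - trend
  list(trace = resid, fit = trend, params = params, model = model,
       rss = sum(resid^2))
}

#' Z-score a trace by its own mean and standard deviation
#'
#' @param trace numeric vector
#' @return `(x - mean) / sd`; when the SD is zero the values are returned as
#'   zeros with attribute `degenerate = TRUE`
#' @export
zscore <- function(trace) {
  s <- stats::sd(trace)
  if (!is.finite(s) || s == 0) {
    out <- rep(0, length(trace))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (trace - mean(trace)) / s
}

#' Isosbestic movement-artifact check
#'
#' The isosbestic excitation channel is activity-independent, so any sizable
#' correlation between it and body movement indicates a motion artifact in
#' the optical path. Advisory only; no correction is applied.
#'
#' @param signal processed activity channel (unused in the rule, carried for
#'   the record)
#' @param isosbestic processed isosbestic channel
#' @param movement z-scored movement metric, aligned
#' @param threshold absolute-correlation flag threshold (default 0.3)
#' @return list with `flagged`, `r` (isosbestic-movement correlation),
#'   `threshold`
#' @export
isosbestic_qc <- function(signal, isosbestic, movement, threshold = 0.3) {
  stopifnot(length(isosbestic) == length(movement))
  r <- stats::cor(isosbestic, movement)
  list(flagged = is.finite(r) && abs(r) > threshold, r = r,
       threshold = threshold)
}

#' Full photometry preprocessing chain
#'
#' Trim first minute, detrend both channels with the exponential model,
#' z-score both. Returns a `photometry_trace`.
#'
#' @param signal raw activity-channel vector
#' @param isosbestic raw isosbestic-channel vector (optional)
#' @param fs sampling rate in Hz
#' @param trim_s seconds trimmed from the start (default 60)
#' @return object of class `photometry_trace`: list with z-scored `signal`,
#'   `isosbestic` (or NULL), `fs`, `detrend` (per-channel model record)
#' @export
preprocess_photometry <- function(signal, isosbestic = NULL, fs, trim_s = 60) {
  sg <- trim_first_minute(signal, fs, trim_s)
  d_sig <- detrend_triple_exponential(sg, fs)
  out <- list(signal = zscore(d_sig$trace), isosbestic = NULL, fs = fs,
              detrend = list(signal = d_sig$model))
  if (!is.null(isosbestic)) {
    iso <- trim_first_minute(isosbestic, fs, trim_s)
    d_iso <- detrend_triple_exponential(iso, fs)
    out$isosbestic <- zscore(d_iso$trace)
    out$detrend$isosbestic <- d_iso$model
  }
  class(out) <- "photometry_trace"
  out
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("<photometry_trace> %d samples @ %g Hz (detrend: %s)\n",
              length(x$signal), x$fs, x$detrend$signal))
  invisible(x)
}
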