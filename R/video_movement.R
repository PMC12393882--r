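# Video-derived movement metric: frame differencing, indicator-decay kernel,
# z-scoring. The metric is the summed absolute per-pixel difference between
# consecutive frames, convolved with a GCaMP6s-matched exponential decay so
# that it lives on the same effective timescale as the photometry signal.

#' Summed absolute per-pixel frame differences
#'
#' @param frames either a 3-d array (height x width x n_frames) or a list of
#'   equally sized matrices; values must be 8-bit grayscale (integers in
#'   0..255). Double input in 0..255 with integral values is accepted with a
#'   conversion warning.
#' @return object of class `motion_series`: list with `values` (length
#'   n_frames - 1, value t is the difference between frames t and t+1, i.e.
#'   the first frame yields no sample) and `fs = NA` until paired with a rate
#' @export
frame_difference <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  stopifnot(is.list(frames), length(frames) >= 2L)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have mismatched dimensions")
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 255)
    stop("frames are not 8-bit grayscale (values outside 0..255)")
  if (!all(vapply(frames, function(f) all(f == round(f)), logical(1))))
    warning("non-integer pixel values; rounding to 8-bit")
  # widen to double before differencing so 8-bit storage cannot wrap around
  vals <- vapply(seq_len(length(frames) - 1L), function(i) {
    sum(abs(round(frames[[i + 1L]]) - round(frames[[i]])))
  }, numeric(1))
  structure(list(values = vals, fs = NA_real_), class = "motion_series")
}

#' Exponential indicator-decay kernel
#'
#' A 60 s decaying exponential whose half-life matches the reported GCaMP6s
#' half-life of 1.796 s: k(t) = exp(-ln(2) t / half_life), k(0) = 1.
#'
#' @param half_life_s indicator half-life in seconds (default 1.796)
#' @param duration_s kernel support in seconds (default 60)
#' @param fs sampling rate in Hz
#' @return numeric kernel sampled at `t = 0, 1/fs, ...` over `[0, duration_s)`
#' @export
gcamp_kernel <- function(half_life_s = 1.796, duration_s = 60, fs) {
  stopifnot(half_life_s > 0, duration_s * fs >= 2)
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  exp(-log(2) * t / half_life_s)
}

#' Kernel-convolved, z-scored movement metric
#'
#' Causal convolution of the raw motion series with the indicator kernel,
#' removal of the first minute of convolution (transient + photometry trim
#' alignment), then z-scoring by the retained samples' own mean and SD.
#' No smoothing is applied: derived statistics always use the raw metric.
#'
#' @param motion a `motion_series` or numeric vector of raw frame differences
#' @param kernel convolution kernel (see [gcamp_kernel()])
#' @param fs sampling rate in Hz
#' @param trim_s seconds removed from the start of the convolution (default 60)
#' @return object of class `movement_trace`: list with z-scored `values`,
#'   `fs`, `trim_offset` (samples removed) and `degenerate` (TRUE when the
#'   input was constant so the z-score is undefined; `values` are then 0)
#' @export
movement_metric <- function(motion, kernel, fs, trim_s = 60) {
  x <- if (inherits(motion, "motion_series")) motion$values else motion
  stopifnot(is.numeric(x), all(is.finite(x)), fs > 0)
  trim <- as.integer(round(trim_s * fs))
  if (length(x) <= trim) stop("motion series shorter than the trim window")
  conv <- causal_convolve(x, kernel)
  kept <- conv[(trim + 1L):length(conv)]
  s <- stats::sd(kept)
  # constant input leaves only float residue after convolution
  degenerate <- !is.finite(s) || s <= 1e-10 * max(abs(kept), 1)
  vals <- if (degenerate) rep(0, length(kept)) else (kept - mean(kept)) / s
  structure(list(values = vals, fs = fs, trim_offset = trim,
                 degenerate = degenerate),
            class = "movement_trace")
}

#' Display-only moving-average smoothing
#'
#' Centered moving average used for figure rendering (e.g. 250 ms for
#' locomotion, 1 s for photometry). Never feeds statistics.
#'
#' @param series numeric vector
#' @param window_s window length in seconds
#' @param fs sampling rate in Hz
#' @return smoothed numeric vector with attribute `display_only = TRUE`
#' @export
smooth_for_display <- function(series, window_s, fs) {
  k <- max(1L, as.integer(round(window_s * fs)))
  stopifnot(window_s * fs >= 1)
  out <- moving_average(series, k)
  attr(out, "display_only") <- TRUE
  out
}

#' @export
print.movement_trace <- function(x, ...) {
  cat(sprintf("<movement_trace> %d samples @ %g Hz (trimmed %d)%s\n",
              length(x$values), x$fs, x$trim_offset,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}
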