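# Movement-bout detection, small/large k-means clustering, bout-aligned
# baselining, and behavior-label summaries.

#' Detect self-initiated movement bouts
#'
#' A bout onset is the first sample at which the smoothed (1 s moving
#' average) z-scored movement metric reaches >= 0 after at least
#' `quiescence_s` of samples strictly below 0. The threshold is exactly 0 SD
#' on the smoothed metric; no hysteresis is applied.
#'
#' @param movement a `movement_trace` (or numeric z-scored vector with `fs`)
#' @param fs sampling rate, taken from the trace when omitted
#' @param quiescence_s required quiet period before an onset (default 4)
#' @param smooth_samples moving-average window in samples (default 20, i.e.
#'   1 s at 20 Hz)
#' @return object of class `bout_table`: data.frame with `onset` (sample
#'   index into the movement trace) and `onset_s`
#' @export
detect_bouts <- function(movement, fs = NULL, quiescence_s = 4,
                         smooth_samples = 20L) {
  if (inherits(movement, "movement_trace")) {
    fs <- movement$fs
    x <- movement$values
  } else x <- movement
  stopifnot(!is.null(fs))
  sm <- moving_average(x, smooth_samples)
  below <- sm < 0
  q <- as.integer(round(quiescence_s * fs))
  # run[i] = number of consecutive below-threshold samples ending at i
  run <- integer(length(x))
  cnt <- 0L
  for (i in seq_along(x)) {
    cnt <- if (below[i]) cnt + 1L else 0L
    run[i] <- cnt
  }
  idx <- which(!below & c(0L, run[-length(run)]) >= q)
  out <- data.frame(onset = idx, onset_s = (idx - 1L) / fs)
  class(out) <- c("bout_table", "data.frame")
  attr(out, "fs") <- fs
  out
}

#' Cluster bouts into small and large movements
#'
#' K-means (k = 2 by default, 10 restarts, seeded) on the movement-metric
#' window 0-4 s after each onset; the cluster with the larger mean window
#' energy is labeled `"large"`. A scalar peak-amplitude feature is available
#' as an alternative.
#'
#' @param bouts a `bout_table`
#' @param movement the `movement_trace` the bouts were detected on
#' @param k number of clusters (default 2)
#' @param window_s feature window after onset in seconds (default c(0, 4))
#' @param features `"window"` (default, the raw metric samples) or `"peak"`
#' @param seed RNG seed for the k-means restarts
#' @return the `bout_table` with a `cluster` column ("small"/"large" for
#'   k = 2, otherwise "c1"..."ck" ordered by energy); bouts whose window
#'   exceeds the trace are dropped (count in attribute `n_dropped`)
#' @export
cluster_bouts <- function(bouts, movement, k = 2L, window_s = c(0, 4),
                          features = c("window", "peak"), seed = 1L) {
  features <- match.arg(features)
  x <- if (inherits(movement, "movement_trace")) movement$values else movement
  fs <- attr(bouts, "fs")
  w <- as.integer(round(window_s * fs))
  keep <- bouts$onset + w[2] <= length(x) & bouts$onset + w[1] >= 1L
  dropped <- sum(!keep)
  bouts <- bouts[keep, , drop = FALSE]
  n_b <- nrow(bouts)
  if (n_b == 0L) {
    bouts$cluster <- character(0)
    attr(bouts, "n_dropped") <- dropped
    return(bouts)
  }
  feat <- t(vapply(bouts$onset,
                   function(i) x[(i + w[1]):(i + w[2])],
                   numeric(w[2] - w[1] + 1L)))
  if (features == "peak") feat <- matrix(apply(feat, 1, max), ncol = 1)
  if (n_b < k) {
    warning("fewer bouts than clusters; labeling all 'small'")
    bouts$cluster <- rep("small", n_b)
  } else if (k == 1L) {
    bouts$cluster <- rep("small", n_b)
  } else {
    km <- with_seed(seed, {
      uniq <- nrow(unique(round(feat, 12)))
      if (uniq < k) {
        warning("degenerate bout features; single effective cluster")
        NULL
      } else stats::kmeans(feat, centers = k, nstart = 10L)
    })
    if (is.null(km)) {
      bouts$cluster <- rep("small", n_b)
    } else {
      energy <- tapply(rowMeans(feat^2), km$cluster, mean)
      ord <- order(energy)  # ascending energy
      name_map <- if (k == 2L) c("small", "large") else
        paste0("c", seq_len(k))
      lab <- stats::setNames(name_map, names(energy)[ord])
      bouts$cluster <- unname(lab[as.character(km$cluster)])
    }
  }
  attr(bouts, "n_dropped") <- dropped
  attr(bouts, "fs") <- fs
  class(bouts) <- c("bout_table", "data.frame")
  bouts
}

#' Bout-aligned, baseline-normalized trace segments
#'
#' Each bout window of the trace is re-expressed as a z-score relative to
#' its own baseline window (default -3 to -1 s before onset, the interval
#' the bout analyses baseline against).
#'
#' @param trace numeric vector aligned to the bout sample indices
#' @param bouts a `bout_table` (or integer onset vector)
#' @param fs sampling rate
#' @param baseline baseline window in seconds relative to onset
#'   (default c(-3, -1))
#' @param window extraction window in seconds relative to onset
#'   (default c(-4, 8))
#' @return matrix (bouts x samples) with attributes `time_s` and
#'   `n_dropped` (bouts falling outside the trace)
#' @export
align_and_baseline <- function(trace, bouts, fs, baseline = c(-3, -1),
                               window = c(-4, 8)) {
  onsets <- if (is.data.frame(bouts)) bouts$onset else as.integer(bouts)
  w <- as.integer(round(window * fs))
  b <- as.integer(round(baseline * fs))
  ok <- onsets + w[1] >= 1L & onsets + w[2] <= length(trace)
  seg <- t(vapply(onsets[ok], function(i) {
    s <- trace[(i + w[1]):(i + w[2])]
    bl <- trace[(i + b[1]):(i + b[2])]
    mu <- mean(bl)
    sdv <- stats::sd(bl)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    (s - mu) / sdv
  }, numeric(w[2] - w[1] + 1L)))
  if (sum(ok) == 1L) seg <- matrix(seg, nrow = 1)
  attr(seg, "time_s") <- seq(w[1], w[2]) / fs
  attr(seg, "n_dropped") <- sum(!ok)
  seg
}

#' Behavior labels from smoothed class likelihoods
#'
#' Each class likelihood column is smoothed with a moving average (default
#' 4 s) and the per-frame argmax taken. Exact ties resolve to the previous
#' frame's label (first frame: the first class in canonical order).
#'
#' @param likelihoods n x 5 matrix of class probabilities (rows sum to 1)
#' @param fs sampling rate
#' @param smooth_s smoothing window in seconds (default 4)
#' @param classes class names in canonical order
#' @return factor of per-frame labels
#' @export
labels_from_likelihoods <- function(likelihoods, fs, smooth_s = 4,
                                    classes = BEHAVIOR_CLASSES) {
  stopifnot(ncol(likelihoods) == length(classes))
  if (any(abs(rowSums(likelihoods) - 1) > 1e-9))
    stop("likelihood rows must sum to 1")
  k <- max(1L, as.integer(round(smooth_s * fs)))
  sm <- apply(likelihoods, 2, moving_average, k = k)
  n <- nrow(sm)
  lab <- integer(n)
  for (i in seq_len(n)) {
    mx <- max(sm[i, ])
    cand <- which(sm[i, ] >= mx - 0)  # exact tie set
    lab[i] <- if (length(cand) == 1L) cand else {
      prev <- if (i > 1L) lab[i - 1L] else NA_integer_
      if (!is.na(prev) && prev %in% cand) prev else cand[1L]
    }
  }
  factor(classes[lab], levels = classes)
}

#' Behavioral transition probability matrix
#'
#' Counts label changes (self-transitions excluded) and row-normalizes to
#' probabilities. Classes never exited keep an all-zero row, recorded in the
#' attribute `undefined_rows`.
#'
#' @param labels factor of per-frame labels
#' @return 5 x 5 matrix of transition probabilities
#' @export
transition_matrix <- function(labels) {
  stopifnot(length(labels) >= 2L)
  lv <- levels(labels)
  from <- labels[-length(labels)]
  to <- labels[-1L]
  chg <- from != to
  counts <- table(factor(from[chg], levels = lv), factor(to[chg], levels = lv))
  counts <- matrix(as.numeric(counts), length(lv), length(lv),
                   dimnames = dimnames(counts))
  rs <- rowSums(counts)
  P <- counts
  P[rs > 0, ] <- P[rs > 0, , drop = FALSE] / rs[rs > 0]
  attr(P, "undefined_rows") <- lv[rs == 0]
  P
}

#' Trace averages aligned to behavioral transitions
#'
#' Mean and SEM of a trace in windows around each occurrence of the most
#' frequent transition types.
#'
#' @param trace numeric vector aligned to `labels`
#' @param labels factor of per-frame labels
#' @param fs sampling rate
#' @param pre_s,post_s window extent around the transition (default 4 s each)
#' @param top_n number of most frequent transition types kept (default 6)
#' @return named list per transition type ("from->to"), each with `mean`,
#'   `sem`, `n`, `time_s`
#' @export
align_to_transitions <- function(trace, labels, fs, pre_s = 4, post_s = 4,
                                 top_n = 6L) {
  stopifnot(length(trace) == length(labels))
  n <- length(labels)
  idx <- which(labels[-1L] != labels[-n]) + 1L
  w1 <- as.integer(round(pre_s * fs))
  w2 <- as.integer(round(post_s * fs))
  idx <- idx[idx - w1 >= 1L & idx + w2 <= n]
  if (length(idx) == 0L) return(list())
  type <- paste0(labels[idx - 1L], "->", labels[idx])
  keep_types <- names(sort(table(type), decreasing = TRUE))
  keep_types <- keep_types[seq_len(min(top_n, length(keep_types)))]
  ts <- seq(-w1, w2) / fs
  out <- lapply(keep_types, function(ty) {
    ii <- idx[type == ty]
    seg <- t(vapply(ii, function(i) trace[(i - w1):(i + w2)],
                    numeric(w1 + w2 + 1L)))
    if (length(ii) == 1L) seg <- matrix(seg, nrow = 1)
    list(mean = colMeans(seg),
         sem = apply(seg, 2, stats::sd) / sqrt(nrow(seg)),
         n = nrow(seg), time_s = ts)
  })
  stats::setNames(out, keep_types)
}

#' Per-behavior-class trace means
#'
#' @param trace numeric vector aligned to `labels`
#' @param labels factor of per-frame labels
#' @return named numeric vector of class means (NA for absent classes)
#' @export
behavior_means <- function(trace, labels) {
  stopifnot(length(trace) == length(labels))
  vapply(levels(labels), function(cl) {
    i <- labels == cl
    if (!any(i)) NA_real_ else mean(trace[i])
  }, numeric(1))
}
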