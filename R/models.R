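# Session-level statistics: whole-session correlation, cross-correlation
# lag with IQR outlier filtering, the three mixed-effects models compared by
# AIC, glucose preprocessing, the per-IMF movement/glucose multiplexing
# regression, the glucose-percentile interaction, PLS drop-one feature
# contributions, and circular regression of phase on log-frequency.

#' Whole-session Pearson correlation
#'
#' All samples of both traces across the recording, optionally restricted by
#' a mask (e.g. non-locomotor epochs).
#'
#' @param photometry numeric vector
#' @param covariate numeric vector, same length
#' @param mask optional logical vector selecting samples
#' @return Pearson r, or NA when fewer than 3 valid samples remain
#' @export
session_correlation <- function(photometry, covariate, mask = NULL) {
  stopifnot(length(photometry) == length(covariate))
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(photometry))
    photometry <- photometry[mask]
    covariate <- covariate[mask]
  }
  ok <- is.finite(photometry) & is.finite(covariate)
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(photometry[ok], covariate[ok])
}

#' Average per-session correlations by subject
#'
#' @param r per-session correlation values
#' @param subject matching subject identifiers
#' @return named vector of per-subject mean correlations
#' @export
subject_mean_correlation <- function(r, subject) {
  m <- tapply(r, subject, mean, na.rm = TRUE)
  stats::setNames(as.numeric(m), names(m))
}

#' Cross-correlation lag between photometry and movement
#'
#' Normalized cross-correlation over +-`max_lag_s`; the reported lag
#' maximizes the correlation. Negative lags mean photometry precedes
#' movement.
#'
#' @param photometry,movement aligned numeric traces
#' @param fs sampling rate
#' @param max_lag_s search half-window in seconds (default 10)
#' @return list with `lag_s`, `peak_r`
#' @export
crosscorr_lag <- function(photometry, movement, fs, max_lag_s = 10) {
  stopifnot(length(photometry) == length(movement))
  if (stats::sd(photometry) == 0 || stats::sd(movement) == 0)
    return(list(lag_s = NA_real_, peak_r = NA_real_))
  cc <- stats::ccf(photometry, movement,
                   lag.max = as.integer(round(max_lag_s * fs)),
                   plot = FALSE, demean = TRUE)
  i <- which.max(cc$acf)
  list(lag_s = cc$lag[i] / fs, peak_r = as.numeric(cc$acf[i]))
}

#' Flag outlying subjects by the 1.5 x IQR rule
#'
#' @param values per-subject statistics (e.g. lag times)
#' @return logical vector, TRUE where the value falls outside
#'   `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
#' @export
iqr_outliers <- function(values) {
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' Mixed-effects model comparison of behavior vs movement predictors
#'
#' Fits, by maximum likelihood, (1) photometry ~ behavior with a random
#' intercept per subject; (2) photometry ~ movement with a random movement
#' slope; (3) photometry ~ movement + behavior with random intercept and
#' slope; and returns their AICs. ML rather than REML because the fixed
#' effects differ across models.
#'
#' @param photometry,movement aligned numeric vectors over all subjects
#' @param behavior factor of behavior classes
#' @param subject subject identifiers (>= 2 distinct)
#' @return list with `aic` (named, model1..model3), `fits`, `singular`
#'   (logical per model)
#' @export
lmm_aic_trio <- function(photometry, movement, behavior, subject) {
  stopifnot(length(unique(subject)) >= 2L)
  d <- data.frame(y = photometry, mov = movement,
                  beh = factor(behavior), subj = factor(subject))
  m1 <- lme4::lmer(y ~ beh + (1 | subj), data = d, REML = FALSE)
  m2 <- lme4::lmer(y ~ mov + (0 + mov | subj), data = d, REML = FALSE)
  m3 <- lme4::lmer(y ~ mov + beh + (1 + mov | subj), data = d, REML = FALSE)
  fits <- list(model1 = m1, model2 = m2, model3 = m3)
  list(aic = vapply(fits, stats::AIC, numeric(1)),
       fits = fits,
       singular = vapply(fits, lme4::isSingular, logical(1)))
}

#' Preprocess sparse glucose telemetry
#'
#' Missing samples are linearly interpolated, the trace resampled onto the
#' photometry time base, smoothed with a 10 min moving average, and the
#' first derivative taken from the smoothed trace (mM/s).
#'
#' @param glucose data.frame with `time_s` and `mM` (NA = missing sample)
#' @param fs_target photometry sampling rate (Hz)
#' @param t_grid optional explicit target time grid (s)
#' @param smooth_min smoothing window in minutes (default 10)
#' @return list with `time_s`, `glucose` (resampled), `smoothed`,
#'   `derivative` (mM/s, same length)
#' @export
glucose_preprocess <- function(glucose, fs_target, t_grid = NULL,
                               smooth_min = 10) {
  ok <- is.finite(glucose$mM)
  if (sum(ok) < 2L) stop("need at least 2 glucose samples")
  if (is.null(t_grid))
    t_grid <- seq(min(glucose$time_s), max(glucose$time_s), by = 1 / fs_target)
  g <- stats::approx(glucose$time_s[ok], glucose$mM[ok], xout = t_grid,
                     rule = 2)$y
  k <- max(1L, as.integer(round(smooth_min * 60 * fs_target)))
  sm <- moving_average(g, k)
  deriv <- c(diff(sm), NA) * fs_target
  deriv[length(deriv)] <- deriv[length(deriv) - 1L]
  list(time_s = t_grid, glucose = g, smoothed = sm, derivative = deriv)
}

#' Per-IMF regression on glucose derivative and movement
#'
#' Ordinary least squares IMF_n = b0 + b1 * glucose derivative +
#' b2 * movement, with both predictors z-scored so the weights are
#' comparable, recorded against each IMF's characteristic frequency.
#'
#' @param iset an `imf_set` of the photometry signal
#' @param derivative glucose first derivative aligned to the IMF samples
#' @param movement z-scored movement metric aligned to the IMF samples
#' @return data.frame with `imf`, `char_freq_hz`, `beta_glucose`,
#'   `beta_movement`, `se_glucose`, `se_movement`; attribute `collinear` is
#'   TRUE when |r| between the predictors exceeds 0.99
#' @export
imf_multiplex_fit <- function(iset, derivative, movement) {
  stopifnot(inherits(iset, "imf_set"),
            length(derivative) == ncol(iset$imfs),
            length(movement) == ncol(iset$imfs))
  x1 <- zscore(derivative)
  x2 <- zscore(movement)
  deg1 <- isTRUE(attr(x1, "degenerate"))
  deg2 <- isTRUE(attr(x2, "degenerate"))
  if (deg1 || deg2)
    warning("constant predictor; its weights are undefined")
  collinear <- !deg1 && !deg2 && abs(stats::cor(x1, x2)) > 0.99
  if (collinear) warning("glucose derivative and movement are collinear")
  grab <- function(cf, row, col) {
    if (row %in% rownames(cf)) cf[row, col] else NA_real_
  }
  rows <- lapply(seq_len(nrow(iset$imfs)), function(k) {
    fit <- stats::lm(iset$imfs[k, ] ~ x1 + x2)
    cf <- summary(fit)$coefficients
    data.frame(imf = k, char_freq_hz = iset$char_freq[k],
               beta_glucose = grab(cf, "x1", 1),
               beta_movement = grab(cf, "x2", 1),
               se_glucose = grab(cf, "x1", 2),
               se_movement = grab(cf, "x2", 2))
  })
  out <- do.call(rbind, rows)
  attr(out, "collinear") <- collinear
  out
}

#' Bin multiplex weights into frequency bands
#'
#' Mean per-band weights per subject: the higher-frequency band (0.01-0.1
#' Hz) carries movement information, the sub-millihertz band glucose.
#'
#' @param fit output of [imf_multiplex_fit()], optionally row-bound over
#'   subjects with a `subject` column
#' @param bands named list of `c(lo, hi)` frequency intervals in Hz
#' @return data.frame with one row per (subject x) band: mean
#'   `beta_glucose`, `beta_movement`, `n_imfs`
#' @export
bin_multiplex_weights <- function(fit,
                                  bands = list(high = c(1e-2, 1e-1),
                                               low = c(0, 1e-3))) {
  if (is.null(fit$subject)) fit$subject <- 1L
  out <- do.call(rbind, lapply(split(fit, fit$subject), function(d) {
    do.call(rbind, lapply(names(bands), function(b) {
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      i <- is.finite(d$char_freq_hz) & d$char_freq_hz >= lo &
        d$char_freq_hz < hi
      data.frame(subject = d$subject[1], band = b,
                 beta_glucose = if (any(i)) mean(d$beta_glucose[i]) else NA,
                 beta_movement = if (any(i)) mean(d$beta_movement[i]) else NA,
                 n_imfs = sum(i))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Movement x blood-glucose-percentile interaction
#'
#' Within-session percentile rank of the smoothed glucose trace, then OLS of
#' photometry on movement, percentile and their interaction. The interaction
#' coefficient asks whether movement encoding scales with glycemia.
#'
#' @param photometry,movement aligned numeric vectors
#' @param glucose_smoothed smoothed glucose aligned to the same samples
#' @return list with `interaction`, `se`, `coefficients`, `degenerate`
#' @export
percentile_interaction <- function(photometry, movement, glucose_smoothed) {
  stopifnot(length(photometry) == length(movement),
            length(photometry) == length(glucose_smoothed))
  if (stats::sd(glucose_smoothed) == 0 || stats::sd(movement) == 0)
    return(list(interaction = NA_real_, se = NA_real_,
                coefficients = NULL, degenerate = TRUE))
  pct <- 100 * (rank(glucose_smoothed) - 0.5) / length(glucose_smoothed)
  fit <- stats::lm(photometry ~ movement * pct)
  cf <- summary(fit)$coefficients
  list(interaction = cf["movement:pct", 1], se = cf["movement:pct", 2],
       coefficients = stats::coef(fit), degenerate = FALSE)
}

#' PLS drop-one feature contributions
#'
#' Two-component partial least squares regression of photometry on the
#' feature matrix; R2_full is the mean R2 over a seeded fivefold
#' cross-validation; each feature is dropped in turn for R2_partial and the
#' percentage contribution of feature k is
#' 100 (1 - R2_partial_k / R2_full) / sum_j (1 - R2_partial_j / R2_full),
#' so contributions sum to 100.
#'
#' @param features numeric matrix or data.frame (n x p, p >= 3, named
#'   columns)
#' @param target photometry vector
#' @param ncomp PLS components (default 2)
#' @param folds cross-validation folds (default 5)
#' @param seed fold-assignment seed
#' @return list with `contributions` (named, sums to 100), `R2_full`,
#'   `R2_partial`, `defined` (FALSE when R2_full <= 0)
#' @export
pls_drop_one <- function(features, target, ncomp = 2L, folds = 5L,
                         seed = 1L) {
  X <- as.matrix(features)
  stopifnot(ncol(X) >= 3L, nrow(X) == length(target))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(X))))
  cv_r2 <- function(Xm) {
    nc <- min(ncomp, ncol(Xm), qr(scale(Xm))$rank)
    r2 <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- mixOmics::pls(Xm[tr, , drop = FALSE], target[tr], ncomp = nc,
                           mode = "regression", scale = TRUE)
      pr <- stats::predict(fit, Xm[!tr, , drop = FALSE])$predict[, 1, nc]
      yte <- target[!tr]
      1 - sum((yte - pr)^2) / sum((yte - mean(yte))^2)
    }, numeric(1))
    mean(r2)
  }
  R2_full <- cv_r2(X)
  R2_partial <- vapply(seq_len(ncol(X)), function(k)
    cv_r2(X[, -k, drop = FALSE]), numeric(1))
  names(R2_partial) <- colnames(X)
  if (!is.finite(R2_full) || R2_full <= 0) {
    return(list(contributions = stats::setNames(rep(NA_real_, ncol(X)),
                                                colnames(X)),
                R2_full = R2_full, R2_partial = R2_partial, defined = FALSE))
  }
  loss <- 1 - R2_partial / R2_full
  if (abs(sum(loss)) < 1e-9) {
    # dropping any feature changes nothing (e.g. duplicated features):
    # the normalization is 0/0 and the symmetric limit is an even split
    contributions <- stats::setNames(rep(100 / ncol(X), ncol(X)),
                                     colnames(X))
  } else {
    contributions <- 100 * loss / sum(loss)
  }
  list(contributions = contributions, R2_full = R2_full,
       R2_partial = R2_partial, defined = TRUE)
}

#' Circular regression of preferred phase on log-frequency
#'
#' Phase is encoded as (sin, cos) and each component regressed on
#' log10(frequency) with a kernel support-vector regressor; predictions are
#' renormalized to unit length and the phase recovered by atan2, which keeps
#' the fit continuous across the 0/2pi wrap.
#'
#' @param char_freqs characteristic frequencies (Hz)
#' @param phases preferred phases (radians); NA pairs are dropped
#' @param n_grid evaluation grid size on the log-frequency axis (default 7)
#' @param method `"svr"` (default) or `"loess"`
#' @return data.frame with `log10_freq`, `freq_hz`, `phase` in [0, 2pi)
#' @export
circular_regression <- function(char_freqs, phases, n_grid = 7L,
                                method = c("svr", "loess")) {
  method <- match.arg(method)
  ok <- is.finite(char_freqs) & is.finite(phases) & char_freqs > 0
  stopifnot(sum(ok) >= n_grid)
  x <- log10(char_freqs[ok])
  s <- sin(phases[ok]); cth <- cos(phases[ok])
  grid <- seq(min(x), max(x), length.out = n_grid)
  if (method == "svr") {
    # a constant response (all phases equal) has zero variance; fit it as
    # its mean rather than passing a non-scalable target to the SVR
    fit1 <- function(y) {
      if (stats::sd(y) < 1e-12) return(rep(mean(y), n_grid))
      stats::predict(e1071::svm(x = matrix(x), y = y,
                                type = "eps-regression"), matrix(grid))
    }
    ps <- fit1(s)
    pc <- fit1(cth)
  } else {
    d <- data.frame(x = x, s = s, cth = cth)
    ps <- stats::predict(stats::loess(s ~ x, d), data.frame(x = grid))
    pc <- stats::predict(stats::loess(cth ~ x, d), data.frame(x = grid))
  }
  nrm <- sqrt(ps^2 + pc^2)
  nrm[nrm == 0] <- 1
  data.frame(log10_freq = grid, freq_hz = 10^grid,
             phase = atan2(ps / nrm, pc / nrm) %% (2 * pi))
}
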