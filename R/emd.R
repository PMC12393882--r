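
# ---- internal helpers -------------------------------------------------------

#' Indices of local maxima and minima
#'
#' Plateaus are handled by forward-filling zero first differences, so a flat
#' crest yields a single extremum at its first sample.
#' @param x numeric vector
#' @return list with integer vectors `max` and `min`
#' @keywords internal
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) == 0L) return(list(max = integer(0), min = integer(0)))
  # forward-fill zeros with the last nonzero slope sign
  idx <- cummax(ifelse(s != 0, seq_along(s), 0L))
  idx[idx == 0L] <- nz[1L]
  s <- s[idx]
  turns <- diff(s)
  list(max = which(turns < 0) + 1L, min = which(turns > 0) + 1L)
}

# cubic-spline envelope through (t, v) extrema, mirrored about both ends of
# 1..n to suppress end swings; returns the envelope evaluated at 1..n
envelope_spline <- function(t, v, n) {
  k <- length(t)
  if (k == 0L) return(rep(0, n))
  if (k == 1L) return(rep(v, n))
  nm <- min(k, 2L)
  tl <- 2 - rev(t[seq_len(nm)])          # mirror about sample 1
  vl <- rev(v[seq_len(nm)])
  tr <- 2 * n - rev(t[k - seq_len(nm) + 1L])  # mirror about sample n
  vr <- rev(v[k - seq_len(nm) + 1L])
  tt <- c(tl, t, tr)
  vv <- c(vl, v, vr)
  keep <- !duplicated(tt)
  stats::spline(tt[keep], vv[keep], xout = seq_len(n), method = "fmm")$y
}

# discrete analytic signal via FFT (Marple): positive frequencies doubled
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

# ---- sifting ----------------------------------------------------------------

#' Empirical mode decomposition by sifting
#'
#' Decomposes a (z-scored) signal into intrinsic mode functions (IMFs) using
#' the classic sifting procedure: cubic-spline envelopes through the local
#' extrema, subtraction of the envelope mean, iterated until the Cauchy
#' stopping criterion is met, then subtraction of the accepted IMF from the
#' running residual. IMFs come out ordered fast to slow. The decomposition is
#' exactly additive: `colSums` of the IMFs plus the residual reconstructs the
#' input to floating-point precision.
#'
#' @param x numeric signal, expected z-scored (decomposition itself does not
#'   require it, but downstream statistics assume comparable units)
#' @param fs sampling rate in Hz
#' @param max_imfs maximum number of IMFs to extract (default 12)
#' @param sd_thresh Cauchy criterion on successive sift iterates
#'   (default 0.2)
#' @param max_iter maximum sift iterations per IMF (default 50)
#' @return an object of class `imf_set`: list with `imfs` (n_imfs x n matrix,
#'   possibly 0-row for monotone input), `residual`, `fs`, and per-IMF
#'   instantaneous `phase`, `amplitude`, `frequency` matrices, `freq_mask`
#'   (TRUE where instantaneous frequency is reliable), `char_freq` (Hz) and
#'   `power_pct`
#' @export
sift <- function(x, fs, max_imfs = 12L, sd_thresh = 0.2, max_iter = 50L) {
  stopifnot(is.numeric(x), all(is.finite(x)), fs > 0)
  n <- length(x)
  if (n < 64L) stop("signal too short for sifting (need >= 64 samples)")
  resid <- as.numeric(x)
  imfs <- list()
  for (k in seq_len(max_imfs)) {
    ext <- local_extrema(resid)
    if (length(ext$max) + length(ext$min) < 3L) break
    h <- resid
    for (it in seq_len(max_iter)) {
      e <- local_extrema(h)
      if (length(e$max) < 2L || length(e$min) < 2L) break
      upper <- envelope_spline(e$max, h[e$max], n)
      lower <- envelope_spline(e$min, h[e$min], n)
      m <- (upper + lower) / 2
      denom <- sum(h^2)
      if (denom == 0) break
      crit <- sum(m^2) / denom
      h <- h - m
      if (crit < sd_thresh) break
    }
    imfs[[k]] <- h
    resid <- resid - h
  }
  out <- list(
    imfs = if (length(imfs)) do.call(rbind, imfs) else
      matrix(numeric(0), nrow = 0, ncol = n),
    residual = resid, fs = fs, input = as.numeric(x)
  )
  class(out) <- "imf_set"
  attach_attributes(out)
}

# compute instantaneous attributes + summaries for every IMF in the set
attach_attributes <- function(iset) {
  ni <- nrow(iset$imfs)
  n <- ncol(iset$imfs)
  iset$phase <- matrix(NA_real_, ni, n)
  iset$amplitude <- matrix(NA_real_, ni, n)
  iset$frequency <- matrix(NA_real_, ni, n)
  iset$freq_mask <- matrix(FALSE, ni, n)
  iset$char_freq <- rep(NA_real_, ni)
  for (k in seq_len(ni)) {
    at <- instantaneous_attributes(iset$imfs[k, ], iset$fs)
    iset$phase[k, ] <- at$phase
    iset$amplitude[k, ] <- at$amplitude
    iset$frequency[k, ] <- at$frequency
    iset$freq_mask[k, ] <- at$mask
    iset$char_freq[k] <- characteristic_frequency(at$frequency[at$mask],
                                                  at$amplitude[at$mask])
  }
  iset$power_pct <- imf_power(iset)
  iset
}

#' Instantaneous phase, amplitude and frequency of one IMF
#'
#' Normalized Hilbert transform: the amplitude envelope is a cubic spline
#' through the maxima of |imf|, iterated (up to 3 passes) until the
#' normalized carrier lies within [-1, 1]; phase is the unwrapped argument
#' of the carrier's analytic signal, rotated by +pi/2 so that a crest maps to
#' pi/2 and a trough to 3*pi/2 (upstate/downstate convention); frequency is
#' the phase gradient clipped at 0. Samples where the envelope is near zero
#' (below 1e-3 of its maximum) carry unreliable frequency and are masked.
#'
#' @param imf numeric vector (one intrinsic mode function)
#' @param fs sampling rate (Hz)
#' @param convention `"upstate"` (crest at pi/2, default) or `"hilbert"`
#'   (raw analytic-signal phase, crest at 0)
#' @return list with `phase` (radians in [0, 2*pi)), `amplitude`,
#'   `frequency` (Hz, >= 0), `mask` (TRUE = frequency reliable)
#' @export
instantaneous_attributes <- function(imf, fs,
                                     convention = c("upstate", "hilbert")) {
  convention <- match.arg(convention)
  n <- length(imf)
  stopifnot(n >= 4L, all(is.finite(imf)), fs > 0)
  env <- rep(1, n)
  carrier <- imf
  for (pass in 1:3) {
    a <- abs(carrier)
    pk <- local_extrema(a)$max
    pk <- union(pk, which(a >= max(a) * (1 - 1e-12)))  # global max always a knot
    pk <- sort(pk)
    if (length(pk) < 2L) {
      e <- rep(max(a), n)
    } else {
      e <- envelope_spline(pk, a[pk], n)
    }
    # envelope must dominate the signal pointwise: spline undershoot between
    # knots would otherwise send the normalized carrier outside [-1, 1] and
    # make subsequent passes diverge
    e <- pmax(e, a, max(a) * 1e-8)
    env <- env * e
    carrier <- carrier / e
    if (max(abs(carrier)) <= 1 + 1e-6) break
  }
  carrier <- pmax(pmin(carrier, 1), -1)
  z <- analytic_signal(carrier)
  ph_raw <- unwrap_phase(Arg(z))
  freq <- c(diff(ph_raw), NA) * fs / (2 * pi)
  freq[n] <- freq[n - 1L]
  freq <- pmax(freq, 0)
  amp <- env
  mask <- amp > max(amp) * 1e-3
  ph <- if (convention == "upstate") ph_raw + pi / 2 else ph_raw
  list(phase = ph %% (2 * pi), amplitude = amp, frequency = freq, mask = mask)
}

#' Amplitude-weighted mean instantaneous frequency
#'
#' @param frequency instantaneous frequency samples (Hz), masked samples
#'   already removed
#' @param amplitude matching amplitude samples (weights)
#' @return characteristic frequency in Hz, or `NA` when all weights vanish
#' @export
characteristic_frequency <- function(frequency, amplitude) {
  stopifnot(length(frequency) == length(amplitude))
  w <- sum(amplitude)
  if (length(frequency) == 0L || w == 0) return(NA_real_)
  sum(amplitude * frequency) / w
}

#' Relative power of each IMF
#'
#' Power of an IMF is the mean of its squared instantaneous amplitude,
#' expressed as a percentage of the total over all IMFs in the set.
#'
#' @param iset an `imf_set`
#' @return numeric vector summing to 100 (length 0 when there are no IMFs)
#' @export
imf_power <- function(iset) {
  stopifnot(inherits(iset, "imf_set"))
  if (nrow(iset$imfs) == 0L) return(numeric(0))
  p <- rowMeans(iset$amplitude^2)
  100 * p / sum(p)
}

#' Drop extremely slow IMFs from circular statistics
#'
#' IMFs whose characteristic frequency falls below `cutoff` complete too few
#' cycles for phase statistics and are excluded from them; they are retained
#' in the set itself (reconstruction, and the low-frequency regression bin,
#' still use them). Returns the set with a logical `phase_eligible` vector.
#'
#' @param iset an `imf_set`
#' @param cutoff frequency cutoff in Hz (default 1e-3)
#' @return the `imf_set` with `phase_eligible` set
#' @export
exclude_slow_imfs <- function(iset, cutoff = 1e-3) {
  stopifnot(inherits(iset, "imf_set"))
  iset$phase_eligible <- !is.na(iset$char_freq) & iset$char_freq >= cutoff
  iset
}

#' Phase preference of movement within an IMF cycle
#'
#' The first trigonometric circular moment of the IMF's instantaneous phase,
#' weighted by the signed z-scored movement metric: active epochs use
#' `max(m, 0)` as weights, quiescent epochs `max(-m, 0)`. The moment's
#' argument is the preferred phase (crest = pi/2 under the package phase
#' convention) and its modulus the coupling strength in [0, 1].
#'
#' @param phase instantaneous phase samples in radians
#' @param movement z-scored movement metric aligned sample-wise to `phase`
#' @param condition `"active"` or `"quiescent"`
#' @return list with `preferred_phase` ([0, 2*pi)), `coupling_strength`,
#'   `condition`, `defined` (FALSE when all weights vanish)
#' @export
phase_preference <- function(phase, movement,
                             condition = c("active", "quiescent")) {
  condition <- match.arg(condition)
  stopifnot(length(phase) == length(movement))
  w <- if (condition == "active") pmax(movement, 0) else pmax(-movement, 0)
  sw <- sum(w)
  if (sw == 0) {
    return(list(preferred_phase = NA_real_, coupling_strength = NA_real_,
                condition = condition, defined = FALSE))
  }
  M <- sum(w * exp(1i * phase)) / sw
  list(preferred_phase = Arg(M) %% (2 * pi),
       coupling_strength = Mod(M),
       condition = condition, defined = TRUE)
}

#' Index of the maximum-power IMF
#'
#' Ties (equal power to within 1e-12) are broken toward the IMF with higher
#' characteristic frequency.
#'
#' @param iset an `imf_set`
#' @return integer index into the IMF rows
#' @export
max_power_imf <- function(iset) {
  stopifnot(inherits(iset, "imf_set"), nrow(iset$imfs) >= 1L)
  p <- iset$power_pct
  cand <- which(p >= max(p) - 1e-12)
  if (length(cand) == 1L) return(cand)
  cand[which.max(iset$char_freq[cand])]
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs over %d samples @ %g Hz\n",
              nrow(x$imfs), ncol(x$imfs), x$fs))
  if (nrow(x$imfs)) {
    df <- data.frame(imf = seq_len(nrow(x$imfs)),
                     char_freq_hz = signif(x$char_freq, 3),
                     power_pct = round(x$power_pct, 2))
    print(df, row.names = FALSE)
  }
  invisible(x)
}
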