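# shared internal numerics

#' Centered moving average with partial edge windows
#'
#' Edge samples average over the available part of the window, so the output
#' has no NA padding and a constant series is returned unchanged.
#' @param x numeric vector
#' @param k window length in samples (>= 1)
#' @return numeric vector, same length as `x`
#' @keywords internal
moving_average <- function(x, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  n <- length(x)
  if (k == 1L || n == 0L) return(x)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# causal convolution: y[t] = sum_j x[t-j+1] * k[j], truncated to length(x);
# FFT-based with padding to a highly composite length (a prime-length FFT
# would be quadratic)
causal_convolve <- function(x, kern) {
  n <- length(x)
  m <- length(kern)
  nfft <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(x, numeric(nfft - n)))
  K <- stats::fft(c(kern, numeric(nfft - m)))
  Re(stats::fft(X * K, inverse = TRUE))[seq_len(n)] / nfft
}

# save/restore the global RNG state around seeded generation
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
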