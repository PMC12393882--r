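# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# generate a session and run the movement + photometry chain on it
session_chain <- function(preset = "movement", seed = 1L, ...) {
  s <- generate_session(session_preset(preset, seed = seed, ...))
  fs <- s$photometry$fs
  mt <- movement_metric(s$motion_raw, gcamp_kernel(fs = fs), fs)
  ph <- preprocess_photometry(s$photometry$signal, s$photometry$isosbestic,
                              fs)
  list(session = s, movement = mt, photometry = ph, fs = fs)
}

# truth bout onsets re-expressed on the trimmed movement-trace time base
truth_onsets_trimmed <- function(session, trim_s = 60) {
  o <- session$truth$bout_onsets_s - trim_s
  o[o > 4]
}

# two equal-amplitude tones with seeded random phases
two_tone <- function(seed, f1 = 0.2, f2 = 0.02, fs = 5, dur = 600) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  ph <- stats::runif(2, 0, 2 * pi)
  x <- sin(2 * pi * f1 * t + ph[1]) + sin(2 * pi * f2 * t + ph[2])
  as.numeric(scale(x))
}

circ_diff <- function(a, b) Arg(exp(1i * (a - b)))
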