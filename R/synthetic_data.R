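# Synthetic session generator. Produces head-fixed-mouse-style sessions with
# known ground truth: a shot-noise movement-bout process, two-channel
# photometry in which the signal channel carries (i) a kernel-convolved copy
# of the movement, (ii) a negatively weighted copy of the smoothed
# blood-glucose derivative, (iii) optional embedded oscillations to which
# movement bouts can be phase-locked, plus triple-exponential bleaching and
# white noise; sparse glucose telemetry; circular pupil landmarks; and a
# Markov chain of behavior-class likelihoods.

BEHAVIOR_CLASSES <- c("resting", "running", "grooming", "chewing", "sniffing")

#' Parameters of a synthetic session
#'
#' Defaults describe a 20 min session at 20 Hz with movement coupled into
#' photometry at unit gain, glucose-derivative coupling that is negative
#' (higher glucose slope suppresses the signal), a 2 bout/min movement
#' process with bimodal (small/large) amplitudes, and sticky behavior
#' labels. The movement coupling passes only fluctuations faster than the
#' glucose band (2 min moving-average high-pass, i.e. negligible gain below 1 mHz), so movement and glucose-derivative
#' information occupy separate frequency bands of the signal channel. All
#' randomness derives from `seed`.
#'
#' @param fs sampling rate (Hz)
#' @param duration session length (s), at least 120
#' @param move_gain photometry gain on the z-scored convolved movement
#' @param move_lead seconds by which photometry precedes movement (positive =
#'   photometry leads)
#' @param gluc_gain photometry gain on the smoothed glucose first derivative
#'   (z-units per mM/s; typically negative)
#' @param osc_freqs,osc_amps embedded oscillation frequencies (Hz) and
#'   amplitudes (z-units); empty for none
#' @param burst_phase oscillation phase (radians, crest = pi/2) at which
#'   movement bursts are centered, or `NA` for phase-free shot noise
#' @param bout_rate movement bouts per minute
#' @param amp_small,amp_large,p_large bimodal bout-amplitude mixture
#' @param burst_sd half-Gaussian bout envelope decay SD (s)
#' @param refractory_s minimum gap enforced between bouts (s). The default
#'   (15 s) leaves room for the convolved tail of a large bout to decay back
#'   below the mean (~6 s) plus the 4 s quiescence that defines a
#'   self-initiated bout, so generated bouts are bouts in the detector's
#'   sense too
#' @param motion_noise_sd SD of the non-negative motion noise floor
#' @param class_motion named per-behavior additive motion level (same units
#'   as bout amplitudes); zero vector decouples behavior from movement
#' @param bleach_params list with amplitudes `a` (length <= 3), time
#'   constants `tau` (s) and offset `c0` of the bleaching trend
#' @param noise_sd additive white-noise SD on the photometry channels
#' @param behavior_transition 5x5 row-stochastic per-frame transition matrix
#' @param gluc_fs glucose telemetry rate (Hz)
#' @param gluc_missing fraction of telemetry samples dropped
#' @param gluc_base baseline glycemia (mM)
#' @param infusion_time glucose-infusion onset (s), `NA` for none
#' @param infusion_height glucose rise magnitude (mM)
#' @param seed RNG seed
#' @return validated list of class `session_params`
#' @export
session_params <- function(fs = 20, duration = 1200,
                           move_gain = 1, move_lead = 0, gluc_gain = -300,
                           osc_freqs = numeric(0), osc_amps = numeric(0),
                           burst_phase = NA_real_,
                           bout_rate = 2, amp_small = 0.5, amp_large = 3,
                           p_large = 0.3, burst_sd = 1, refractory_s = 15,
                           motion_noise_sd = 0.05,
                           class_motion = c(resting = 0, running = 4,
                                            grooming = 1.5, chewing = 0.8,
                                            sniffing = 0.8),
                           bleach_params = list(a = c(2, 1, 0.5),
                                                tau = c(600, 120, 24),
                                                c0 = 1),
                           noise_sd = 0.1,
                           behavior_transition = NULL,
                           gluc_fs = 0.1, gluc_missing = 0.05,
                           gluc_base = 5.5,
                           infusion_time = NA_real_, infusion_height = 3,
                           seed = 1L) {
  if (is.null(behavior_transition)) {
    # sticky chain: ~10 s dwell at 20 Hz, uniform exits
    p_stay <- 1 - 2 / (10 * fs)
    behavior_transition <- matrix((1 - p_stay) / 4, 5, 5)
    diag(behavior_transition) <- p_stay
  }
  p <- list(fs = fs, duration = duration, move_gain = move_gain,
            move_lead = move_lead, gluc_gain = gluc_gain,
            osc_freqs = osc_freqs, osc_amps = osc_amps,
            burst_phase = burst_phase, bout_rate = bout_rate,
            amp_small = amp_small, amp_large = amp_large, p_large = p_large,
            burst_sd = burst_sd, refractory_s = refractory_s,
            motion_noise_sd = motion_noise_sd, class_motion = class_motion,
            bleach_params = bleach_params, noise_sd = noise_sd,
            behavior_transition = behavior_transition, gluc_fs = gluc_fs,
            gluc_missing = gluc_missing, gluc_base = gluc_base,
            infusion_time = infusion_time,
            infusion_height = infusion_height, seed = as.integer(seed))
  validate_session_params(p)
  class(p) <- "session_params"
  p
}

validate_session_params <- function(p) {
  stopifnot(p$fs > 0)
  if (p$duration < 120)
    stop("duration must be >= 120 s: the first-minute trim and the 60 s ",
         "kernel transient must leave data")
  stopifnot(p$p_large >= 0, p$p_large <= 1,
            length(p$osc_freqs) == length(p$osc_amps))
  bt <- p$behavior_transition
  stopifnot(is.matrix(bt), nrow(bt) == 5L, ncol(bt) == 5L)
  if (any(abs(rowSums(bt) - 1) > 1e-9))
    stop("behavior_transition rows must sum to 1")
  invisible(TRUE)
}

#' Preset study conditions
#'
#' Named parameter sets matching the package's three main analyses:
#' \describe{
#'   \item{movement}{default 20 min session, movement-coupled photometry.}
#'   \item{bouts}{movement driven purely by the bout process (no behavioral
#'     motion floor), used for bout detection and size clustering.}
#'   \item{phase}{40 min session whose photometry is an embedded 0.0125 Hz
#'     oscillation plus noise, with unimodal movement bursts phase-locked to
#'     the oscillation crest (pi/2); no glucose coupling, no behavioral
#'     motion modulation; used for phase-preference analyses.}
#'   \item{multiplex}{2 h session at 2 Hz with an intragastric-style glucose
#'     infusion at 30 min; movement in the 0.1-0.01 Hz band and glucose
#'     derivative below 1e-3 Hz, used for the frequency-multiplexing
#'     regression.}
#'   \item{behavior}{movement levels modulated by the behavior chain and
#'     photometry driven by movement only, used for the mixed-model
#'     comparison.}
#' }
#'
#' @param name preset name
#' @param seed RNG seed
#' @param ... overrides forwarded to [session_params()]
#' @return a `session_params` object
#' @export
session_preset <- function(name = c("movement", "bouts", "phase",
                                    "multiplex", "behavior"),
                           seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    movement = list(),
    bouts = list(gluc_gain = 0,
                 class_motion = stats::setNames(rep(0, 5),
                                                BEHAVIOR_CLASSES)),
    phase = list(osc_freqs = 0.0125, osc_amps = 1.5, burst_phase = pi / 2,
                 gluc_gain = 0, move_gain = 0, duration = 2400,
                 p_large = 0, amp_small = 1,
                 class_motion = stats::setNames(rep(0, 5), BEHAVIOR_CLASSES)),
    multiplex = list(fs = 2, duration = 7200, infusion_time = 1800,
                     class_motion = stats::setNames(rep(0, 5),
                                                    BEHAVIOR_CLASSES)),
    behavior = list(fs = 2, duration = 1200, gluc_gain = 0,
                    noise_sd = 0.3))
  do.call(session_params, c(args, list(seed = seed), list(...)))
}

# half-Gaussian burst envelope: instant rise at onset, Gaussian decay
add_bursts <- function(motion, onsets_i, amps, fs, burst_sd) {
  n <- length(motion)
  w <- ceiling(5 * burst_sd * fs)
  shape <- exp(-((0:w) / fs)^2 / (2 * burst_sd^2))
  for (b in seq_along(onsets_i)) {
    i0 <- onsets_i[b]
    i1 <- min(n, i0 + w)
    motion[i0:i1] <- motion[i0:i1] + amps[b] * shape[seq_len(i1 - i0 + 1L)]
  }
  motion
}

markov_labels <- function(n, P) {
  lab <- integer(n)
  lab[1] <- sample.int(5L, 1L)
  u <- stats::runif(n)
  cum <- t(apply(P, 1, cumsum))
  for (i in 2:n) lab[i] <- findInterval(u[i], cum[lab[i - 1L], ]) + 1L
  lab
}

#' Generate a synthetic session
#'
#' Deterministic given the parameter seed; see [session_params()] for the
#' generative model.
#'
#' @param params a `session_params` object
#' @return object of class `synthetic_session`: list with `time`,
#'   `motion_raw` (non-negative), `photometry` (list: `signal`, `isosbestic`,
#'   `fs`), `glucose` (data.frame `time_s`, `mM` with NA for dropped
#'   samples), `pupil` (list of n x 8 matrices `x`, `y`, `conf`),
#'   `behavior` (list: `likelihoods` n x 5, `labels`), and `truth`
#'   (generating params, realized bout onsets/amplitudes/cluster labels, the
#'   embedded oscillation phase series, and each photometry component)
#' @export
generate_session <- function(params) {
  stopifnot(inherits(params, "session_params"))
  p <- params
  with_seed(p$seed, {
    n <- as.integer(round(p$duration * p$fs))
    tt <- (seq_len(n) - 1) / p$fs

    # behavior chain and likelihoods
    lab <- markov_labels(n, p$behavior_transition)
    lik <- matrix(stats::rexp(n * 5L) * 0.15, n, 5L)
    lik[cbind(seq_len(n), lab)] <- lik[cbind(seq_len(n), lab)] + 1
    lik <- lik / rowSums(lik)
    colnames(lik) <- BEHAVIOR_CLASSES

    # bout onsets: shifted-exponential gaps, optionally phase-locked
    mean_gap <- 60 / p$bout_rate
    if (is.finite(p$burst_phase) && length(p$osc_freqs) >= 1L) {
      # bursts are "centered at burst_phase" as seen by the analysis, i.e.
      # the center of mass of the kernel-convolved burst envelope sits at
      # that oscillation phase; start the burst earlier by that delay
      f1 <- p$osc_freqs[1]
      com_delay <- p$burst_sd * sqrt(2 / pi) + 1.796 / log(2)
      cyc <- seq(0, p$duration * f1)
      cand <- (p$burst_phase / (2 * pi) + cyc) / f1 - com_delay
      keep_p <- min(1, (p$bout_rate / 60) / f1)
      cand <- cand[stats::runif(length(cand)) < keep_p]
      cand <- cand + stats::rnorm(length(cand), 0, 0.02 / f1)
      onsets <- cand[cand > 1 & cand < p$duration - 1]
      if (length(onsets) > 1L)
        onsets <- onsets[c(TRUE, diff(onsets) >= p$refractory_s)]
    } else {
      gaps <- p$refractory_s +
        stats::rexp(ceiling(p$duration / max(mean_gap, 1)) * 3 + 20,
                    1 / max(mean_gap - p$refractory_s, 1))
      onsets <- cumsum(gaps) + 61  # leave the trimmed first minute quiet
      onsets <- onsets[onsets < p$duration - 1]
    }
    n_b <- length(onsets)
    is_large <- stats::runif(n_b) < p$p_large
    amps <- ifelse(is_large, p$amp_large, p$amp_small) *
      exp(stats::rnorm(n_b, 0, 0.1))

    # raw motion: bursts + behavior-dependent floor + non-negative noise
    kern <- gcamp_kernel(fs = p$fs)
    motion_noise <- abs(stats::rnorm(n, 0, p$motion_noise_sd))
    build_motion <- function(onsets) {
      m <- add_bursts(rep(0, n),
                      pmax(1L, as.integer(round(onsets * p$fs)) + 1L),
                      amps, p$fs, p$burst_sd)
      m + unname(p$class_motion)[lab] + motion_noise
    }
    motion <- build_motion(onsets)
    conv <- causal_convolve(motion, kern)
    mov_comp <- zscore(conv)

    # the movement->photometry coupling carries only fluctuations faster
    # than the glucose band: slow (multi-minute) drifts in overall movement
    # level are not passed into the signal, which is what makes movement and
    # glucose-derivative information occupy separate frequency bands of the
    # same trace
    band_limit <- function(m) zscore(m - moving_average(m, as.integer(
      round(120 * p$fs))))

    # phase-locked sessions: self-calibration so the active-epoch circular
    # mean of the realized movement metric lands on burst_phase. The causal
    # kernel tail makes the metric's above-zero support one-sided, which
    # separates the active and quiescent circular means by a structural
    # angle; that asymmetry is split between the two conditions in
    # proportion to how tightly each is interpreted (active 0.4, quiescent
    # 0.6). Two passes converge the shift.
    if (is.finite(p$burst_phase) && length(p$osc_freqs) >= 1L &&
        length(onsets) > 0L) {
      f1 <- p$osc_freqs[1]
      phi <- (2 * pi * f1 * tt) %% (2 * pi)
      for (pass in 1:2) {
        dev_a <- Arg(exp(1i * (Arg(sum(pmax(mov_comp, 0) * exp(1i * phi))) -
                                 p$burst_phase)))
        dev_q <- Arg(exp(1i * (Arg(sum(pmax(-mov_comp, 0) * exp(1i * phi))) -
                                 p$burst_phase - pi)))
        offs <- 0.6 * dev_a + 0.4 * dev_q
        onsets <- onsets - offs / (2 * pi * f1)
        keep <- onsets > 0.5 & onsets < p$duration - 1
        onsets <- onsets[keep]
        amps <- amps[keep]
        is_large <- is_large[keep]
        motion <- build_motion(onsets)
        conv <- causal_convolve(motion, kern)
        mov_comp <- zscore(conv)
      }
    }
    mov_inject <- band_limit(mov_comp)
    lead_i <- as.integer(round(p$move_lead * p$fs))
    if (lead_i != 0) {
      idx <- pmin(pmax(seq_len(n) + lead_i, 1L), n)
      mov_inject <- mov_inject[idx]
    }

    # glucose: slow drift + optional infusion rise; telemetry is sparse/noisy
    gluc_cont <- p$gluc_base + 0.3 * sin(2 * pi * tt / p$duration +
                                           stats::runif(1, 0, 2 * pi))
    if (is.finite(p$infusion_time)) {
      rise_center <- p$infusion_time + 450
      gluc_cont <- gluc_cont +
        p$infusion_height * stats::plogis((tt - rise_center) / 150)
    }
    sm <- moving_average(gluc_cont, as.integer(round(600 * p$fs)))
    deriv <- c(diff(sm), 0) * p$fs
    gluc_comp <- p$gluc_gain * deriv
    g_times <- seq(0, p$duration - 1 / p$gluc_fs, by = 1 / p$gluc_fs)
    g_vals <- stats::approx(tt, gluc_cont, xout = g_times, rule = 2)$y +
      stats::rnorm(length(g_times), 0, 0.05)
    g_vals[stats::runif(length(g_times)) < p$gluc_missing] <- NA_real_

    # embedded oscillations (phase recorded for the first one)
    osc <- rep(0, n)
    osc_phase <- rep(NA_real_, n)
    if (length(p$osc_freqs)) {
      ph0 <- if (is.finite(p$burst_phase)) rep(0, length(p$osc_freqs)) else
        stats::runif(length(p$osc_freqs), 0, 2 * pi)
      for (i in seq_along(p$osc_freqs))
        osc <- osc + p$osc_amps[i] * sin(2 * pi * p$osc_freqs[i] * tt + ph0[i])
      osc_phase <- (2 * pi * p$osc_freqs[1] * tt + ph0[1]) %% (2 * pi)
    }

    bleach <- p$bleach_params$c0 + Reduce(`+`, Map(
      function(a, tau) a * exp(-tt / tau),
      p$bleach_params$a, p$bleach_params$tau))

    signal <- bleach + p$move_gain * mov_inject + gluc_comp + osc +
      stats::rnorm(n, 0, p$noise_sd)
    isosbestic <- 0.6 * bleach + stats::rnorm(n, 0, p$noise_sd)

    # pupil: slowly wandering circle, blink episodes drop confidence
    r_t <- 20 + 3 * sin(2 * pi * tt / 97 + stats::runif(1, 0, 2 * pi))
    cx <- 60 + 2 * sin(2 * pi * tt / 41 + stats::runif(1, 0, 2 * pi))
    cy <- 45 + 2 * cos(2 * pi * tt / 59 + stats::runif(1, 0, 2 * pi))
    conf_prof <- rep(0.95, n)
    n_blinks <- max(1L, as.integer(p$duration / 120))
    bl_start <- sort(sample.int(n - 10L, n_blinks))
    for (b in bl_start) conf_prof[b:(b + 5L)] <- 0.2
    pupil <- generate_pupil_points(cbind(cx, cy), r_t, n_points = 8L,
                                   jitter_sd = 0.3,
                                   conf_profile = conf_prof,
                                   seed = p$seed + 1L)

    out <- list(
      time = tt, motion_raw = as.numeric(motion),
      photometry = list(signal = signal, isosbestic = isosbestic, fs = p$fs),
      glucose = data.frame(time_s = g_times, mM = g_vals),
      pupil = pupil,
      behavior = list(likelihoods = lik,
                      labels = factor(BEHAVIOR_CLASSES[lab],
                                      levels = BEHAVIOR_CLASSES)),
      truth = list(params = p, bout_onsets_s = onsets,
                   bout_amps = amps,
                   bout_cluster = ifelse(is_large, "large", "small"),
                   osc_phase = osc_phase,
                   components = list(movement = p$move_gain * mov_inject,
                                     glucose = gluc_comp, osc = osc,
                                     bleach = bleach),
                   glucose_continuous = gluc_cont,
                   pupil_truth = list(cx = cx, cy = cy, r = r_t))
    )
    class(out) <- "synthetic_session"
    out
  })
}

#' Render a blob-on-background frame stack from per-frame displacements
#'
#' A Gaussian-intensity blob translated horizontally by the cumulative
#' displacement on a static textured background; zero displacement yields
#' identical consecutive frames. Exercises the frame-differencing metric.
#'
#' @param displacements per-frame shift of the blob (px); frame i sits at
#'   the cumulative sum of the first i displacements
#' @param size frame dimensions c(height, width), default c(48, 64)
#' @param seed RNG seed for the static background
#' @param blob_sd blob Gaussian radius (px)
#' @param blob_amp blob peak intensity above background
#' @return 8-bit integer array (height x width x n_frames)
#' @export
generate_frames <- function(displacements, size = c(48L, 64L), seed = 1L,
                            blob_sd = 4, blob_amp = 120) {
  stopifnot(all(is.finite(displacements)))
  h <- size[1]; w <- size[2]
  n <- length(displacements)
  with_seed(seed, {
    bg <- matrix(as.integer(stats::runif(h * w, 20, 60)), h, w)
    pos <- w / 4 + cumsum(displacements)
    if (any(pos < 1 | pos > w)) {
      warning("blob displacement exceeds frame bounds; clamping")
      pos <- pmin(pmax(pos, 1), w)
    }
    y0 <- h / 2
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), w), h, w)
    frames <- array(0L, dim = c(h, w, n))
    for (i in seq_len(n)) {
      blob <- blob_amp * exp(-((xs - pos[i])^2 + (ys - y0)^2) / (2 * blob_sd^2))
      frames[, , i] <- pmin(255L, as.integer(round(bg + blob)))
    }
    frames
  })
}

#' Generate per-frame pupil landmark sets
#'
#' Eight (by default) points at evenly spaced angles around a circle, with
#' radial Gaussian jitter and per-point confidences drawn around a per-frame
#' base profile; low-profile frames emulate blinks (fewer than three
#' confident points).
#'
#' @param center circle center: length-2 vector or n x 2 matrix (per frame)
#' @param radius circle radius: scalar or length-n vector, > 0
#' @param n_points landmarks per frame (>= 3)
#' @param jitter_sd radial jitter SD (px)
#' @param conf_profile per-frame base confidence (scalar or length-n)
#' @param seed RNG seed
#' @param n_frames number of frames (inferred from vector arguments when
#'   possible)
#' @return list with n x n_points matrices `x`, `y`, `conf`
#' @export
generate_pupil_points <- function(center, radius, n_points = 8L,
                                  jitter_sd = 0.3, conf_profile = 0.95,
                                  seed = 1L, n_frames = NULL) {
  stopifnot(n_points >= 3L, all(radius > 0))
  if (is.null(dim(center))) center <- matrix(center, nrow = 1)
  if (is.null(n_frames))
    n_frames <- max(nrow(center), length(radius), length(conf_profile))
  cx <- rep_len(center[, 1], n_frames)
  cy <- rep_len(center[, 2], n_frames)
  r <- rep_len(radius, n_frames)
  base <- rep_len(conf_profile, n_frames)
  ang <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  with_seed(seed, {
    jit <- matrix(stats::rnorm(n_frames * n_points, 0, jitter_sd),
                  n_frames, n_points)
    rr <- outer(r, rep(1, n_points)) + jit
    x <- outer(cx, rep(1, n_points)) + rr * cos(matrix(ang, n_frames,
                                                       n_points, byrow = TRUE))
    y <- outer(cy, rep(1, n_points)) + rr * sin(matrix(ang, n_frames,
                                                       n_points, byrow = TRUE))
    conf <- matrix(pmin(1, pmax(0, base + stats::rnorm(n_frames * n_points,
                                                       0, 0.03))),
                   n_frames, n_points)
    list(x = x, y = y, conf = conf)
  })
}

#' @export
print.synthetic_session <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(paste0("<synthetic_session> %g s @ %g Hz, %d bouts, ",
                     "move_gain=%g, gluc_gain=%g, seed=%d\n"),
              p$duration, p$fs, length(x$truth$bout_onsets_s),
              p$move_gain, p$gluc_gain, p$seed))
  invisible(x)
}
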