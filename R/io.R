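# Session serialization: columnar text tables for traces, YAML for
# parameters, multi-page 8-bit TIFF for frame stacks. Round-trips are exact
# for integer frames and better than 1e-12 (relative) for floating traces.

#' Write a session to a directory
#'
#' @param session a `synthetic_session`
#' @param dir target directory (created if needed)
#' @param frames optional 8-bit frame array (height x width x n) to store as
#'   a multi-page TIFF
#' @return `dir`, invisibly
#' @export
write_session <- function(session, dir, frames = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- session$photometry$fs
  data.table::fwrite(
    data.table::data.table(time_s = session$time,
                           motion = session$motion_raw,
                           ch465 = session$photometry$signal,
                           ch405 = session$photometry$isosbestic),
    file.path(dir, "traces.tsv"), sep = "\t")
  data.table::fwrite(session$glucose, file.path(dir, "glucose.tsv"),
                     sep = "\t")
  lik <- as.data.frame(session$behavior$likelihoods)
  lik$label <- as.character(session$behavior$labels)
  data.table::fwrite(lik, file.path(dir, "behavior.tsv"), sep = "\t")
  pp <- session$pupil
  k <- ncol(pp$x)
  pup <- data.frame(frame = seq_len(nrow(pp$x)))
  for (j in seq_len(k)) {
    pup[[sprintf("p%d_x", j)]] <- pp$x[, j]
    pup[[sprintf("p%d_y", j)]] <- pp$y[, j]
    pup[[sprintf("p%d_likelihood", j)]] <- pp$conf[, j]
  }
  data.table::fwrite(pup, file.path(dir, "pupil.tsv"), sep = "\t")
  par <- session$truth$params
  par$behavior_transition <- as.vector(par$behavior_transition)
  par$class_motion <- as.list(par$class_motion)
  yaml::write_yaml(unclass(par), file.path(dir, "params.yaml"))
  if (!is.null(frames)) {
    pages <- lapply(seq_len(dim(frames)[3]),
                    function(i) frames[, , i] / 255)
    tiff::writeTIFF(pages, file.path(dir, "frames.tif"),
                    bits.per.sample = 8L)
  }
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir session directory
#' @return a `synthetic_session` (without the generator's `truth`
#'   components beyond the stored params); `frames` attached when present
#' @export
read_session <- function(dir) {
  tr <- data.table::fread(file.path(dir, "traces.tsv"))
  gl <- as.data.frame(data.table::fread(file.path(dir, "glucose.tsv")))
  be <- as.data.frame(data.table::fread(file.path(dir, "behavior.tsv")))
  pu <- as.data.frame(data.table::fread(file.path(dir, "pupil.tsv")))
  par <- yaml::read_yaml(file.path(dir, "params.yaml"))
  par$behavior_transition <- matrix(unlist(par$behavior_transition), 5, 5)
  par$class_motion <- unlist(par$class_motion)
  par$osc_freqs <- as.numeric(unlist(par$osc_freqs))
  par$osc_amps <- as.numeric(unlist(par$osc_amps))
  class(par) <- "session_params"
  k <- (ncol(pu) - 1L) / 3L
  pupil <- list(
    x = as.matrix(pu[, sprintf("p%d_x", seq_len(k))]),
    y = as.matrix(pu[, sprintf("p%d_y", seq_len(k))]),
    conf = as.matrix(pu[, sprintf("p%d_likelihood", seq_len(k))]))
  dimnames(pupil$x) <- dimnames(pupil$y) <- dimnames(pupil$conf) <- NULL
  out <- list(
    time = tr$time_s, motion_raw = tr$motion,
    photometry = list(signal = tr$ch465, isosbestic = tr$ch405,
                      fs = par$fs),
    glucose = gl,
    pupil = pupil,
    behavior = list(
      likelihoods = as.matrix(be[, BEHAVIOR_CLASSES]),
      labels = factor(be$label, levels = BEHAVIOR_CLASSES)),
    truth = list(params = par))
  fr_path <- file.path(dir, "frames.tif")
  if (file.exists(fr_path)) {
    pages <- tiff::readTIFF(fr_path, all = TRUE)
    fr <- array(unlist(lapply(pages, function(p) round(p * 255))),
                dim = c(dim(pages[[1]]), length(pages)))
    storage.mode(fr) <- "integer"
    out$frames <- fr
  }
  class(out) <- "synthetic_session"
  out
}

#' Write an IMF set as text tables
#'
#' Produces `<stem>_imfs.tsv` (wide: time, imf_1..imf_k, residual) and
#' `<stem>_summary.tsv` (per-IMF characteristic frequency, power and phase
#' preference in both movement conditions, when a movement trace is given).
#'
#' @param iset an `imf_set`
#' @param stem output path stem
#' @param movement optional aligned z-scored movement metric for the phase
#'   summary columns
#' @return the summary data.frame, invisibly
#' @export
write_imf_set <- function(iset, stem, movement = NULL) {
  n <- ncol(iset$imfs)
  wide <- data.table::data.table(time_s = (seq_len(n) - 1) / iset$fs)
  for (k in seq_len(nrow(iset$imfs)))
    wide[[sprintf("imf_%d", k)]] <- iset$imfs[k, ]
  wide$residual <- iset$residual
  data.table::fwrite(wide, paste0(stem, "_imfs.tsv"), sep = "\t")
  summ <- data.frame(imf = seq_len(nrow(iset$imfs)),
                     char_freq_hz = iset$char_freq,
                     power_pct = iset$power_pct)
  if (!is.null(movement)) {
    for (cond in c("active", "quiescent")) {
      pp <- lapply(seq_len(nrow(iset$imfs)), function(k)
        phase_preference(iset$phase[k, ], movement, cond))
      summ[[paste0("preferred_phase_", cond)]] <-
        vapply(pp, `[[`, numeric(1), "preferred_phase")
      summ[[paste0("coupling_", cond)]] <-
        vapply(pp, `[[`, numeric(1), "coupling_strength")
    }
  }
  data.table::fwrite(summ, paste0(stem, "_summary.tsv"), sep = "\t")
  invisible(summ)
}
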