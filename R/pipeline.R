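# Stage orchestration: a single flat configuration holding every analysis
# parameter, dependency-ordered execution, and a manifest (config hash,
# seed, timings, QC flags) attached to the results.

PIPELINE_STAGES <- c("simulate", "metric", "preprocess", "emd", "bouts",
                     "behavior", "pupil", "analyze")

STAGE_DEPS <- list(
  simulate = character(0),
  metric = "simulate",
  preprocess = "simulate",
  emd = "preprocess",
  bouts = "metric",
  behavior = "simulate",
  pupil = "simulate",
  analyze = c("metric", "preprocess")
)

#' Build a validated run configuration
#'
#' Defaults are the analysis constants used throughout: 20 Hz sampling,
#' 1.796 s indicator half-life over a 60 s kernel, 60 s trim, 20-sample
#' bout smoothing with 4 s quiescence, k = 2 bout clusters, landmark
#' confidence 0.8, multiplex bands 0.01-0.1 Hz and < 1e-3 Hz, 2 PLS
#' components with fivefold CV, 7-point circular-regression grid. Unknown
#' keys are rejected.
#'
#' @param ... overrides of the defaults
#' @return list of class `run_config`
#' @export
run_config <- function(...) {
  defaults <- list(
    stages = PIPELINE_STAGES,
    fs = 20, half_life_s = 1.796, kernel_s = 60, trim_s = 60,
    smooth_samples = 20L, quiescence_s = 4, k = 2L, conf_min = 0.8,
    bands = list(high = c(1e-2, 1e-1), low = c(0, 1e-3)),
    pls_ncomp = 2L, cv_folds = 5L, phase_grid = 7L,
    qc_threshold = 0.3, slow_imf_cutoff = 1e-3, max_lag_s = 10,
    max_imfs = 12L, seed = 1L,
    session_preset = "movement", session_dir = NULL, out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  bad <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic (or
#' supplied) session and returns every stage output plus a manifest with the
#' configuration hash, seed, stage timings and QC flags. Requesting a stage
#' whose upstream output is absent is an explicit error naming the missing
#' stage.
#'
#' @param config a `run_config`
#' @param session optional `synthetic_session`; when NULL and "simulate" is
#'   requested, one is generated from `config$session_preset` and
#'   `config$seed` (or read from `config$session_dir`)
#' @return list of class `pipeline_result` with stage outputs and `manifest`
#' @export
run_pipeline <- function(config = run_config(), session = NULL) {
  stopifnot(inherits(config, "run_config"))
  stages <- unique(config$stages)
  for (st in stages) {
    need <- setdiff(STAGE_DEPS[[st]], c(stages, if (!is.null(session)) "simulate"))
    if (length(need))
      stop(sprintf("stage '%s' requires missing upstream stage '%s'",
                   st, need[1]))
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  res <- list()
  timings <- numeric(0)
  tic <- function(expr) {
    t0 <- proc.time()[3]
    v <- force(expr)
    list(v = v, dt = proc.time()[3] - t0)
  }
  run_stage <- function(name, expr) {
    r <- tic(expr)
    timings[[name]] <<- unname(r$dt)
    r$v
  }
  for (st in stages) {
    switch(st,
      simulate = {
        if (is.null(session)) {
          session <- if (!is.null(config$session_dir))
            read_session(config$session_dir)
          else generate_session(session_preset(config$session_preset,
                                               seed = config$seed))
        }
        res$session <- run_stage("simulate", session)
      },
      metric = {
        kern <- gcamp_kernel(config$half_life_s, config$kernel_s, config$fs)
        res$movement <- run_stage("metric",
          movement_metric(res$session$motion_raw, kern, config$fs,
                          config$trim_s))
      },
      preprocess = {
        res$photometry <- run_stage("preprocess",
          preprocess_photometry(res$session$photometry$signal,
                                res$session$photometry$isosbestic,
                                config$fs, config$trim_s))
      },
      emd = {
        res$imfs <- run_stage("emd", {
          iset <- sift(res$photometry$signal, config$fs,
                       max_imfs = config$max_imfs)
          exclude_slow_imfs(iset, config$slow_imf_cutoff)
        })
      },
      bouts = {
        res$bouts <- run_stage("bouts", {
          b <- detect_bouts(res$movement,
                            quiescence_s = config$quiescence_s,
                            smooth_samples = config$smooth_samples)
          cluster_bouts(b, res$movement, k = config$k, seed = config$seed)
        })
      },
      behavior = {
        res$behavior <- run_stage("behavior", {
          lab <- labels_from_likelihoods(res$session$behavior$likelihoods,
                                         config$fs)
          list(labels = lab, transition = transition_matrix(lab))
        })
      },
      pupil = {
        res$pupil <- run_stage("pupil", {
          fits <- fit_pupil_frames(res$session$pupil, config$conf_min)
          pupil_traces(fits, config$fs)
        })
      },
      analyze = {
        res$analysis <- run_stage("analyze", {
          mv <- res$movement$values
          sg <- res$photometry$signal
          qc <- isosbestic_qc(sg, res$photometry$isosbestic, mv,
                              config$qc_threshold)
          out <- list(
            correlation = session_correlation(sg, mv),
            lag = crosscorr_lag(sg, mv, config$fs, config$max_lag_s),
            qc = qc)
          if (!is.null(res$imfs)) {
            gp <- glucose_preprocess(
              res$session$glucose, config$fs,
              t_grid = res$session$time[(round(config$trim_s * config$fs) +
                                           1):length(res$session$time)])
            fit <- imf_multiplex_fit(res$imfs, gp$derivative, mv)
            out$multiplex <- fit
            out$multiplex_binned <- bin_multiplex_weights(fit, config$bands)
          }
          out
        })
      })
  }
  res$manifest <- list(
    config = config,
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    timings = timings,
    result_hash = config_hash(res[setdiff(names(res), "manifest")]))
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages:",
      paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  cat("config hash:", x$manifest$config_hash, "\n")
  invisible(x)
}
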