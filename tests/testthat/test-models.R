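test_that("session correlation matches a brute-force formula and handles masks", {
  set.seed(1)
  x <- rnorm(1000)
  y <- 0.5 * x + rnorm(1000)
  brute <- mean((x - mean(x)) * (y - mean(y))) /
    (stats::sd(x) * stats::sd(y)) * 1000 / 999
  expect_equal(session_correlation(y, x), brute, tolerance = 1e-12)
  expect_equal(session_correlation(x, x), 1)
  expect_lt(abs(session_correlation(rnorm(10000), rnorm(10000))), 0.05)
  mask <- seq_along(x) <= 500
  expect_equal(session_correlation(y, x, mask),
               stats::cor(y[1:500], x[1:500]))
  expect_true(is.na(session_correlation(x[1:2], y[1:2])))
  expect_equal(unname(subject_mean_correlation(c(0.2, 0.4, 0.9),
                                               c("a", "a", "b"))),
               c(0.3, 0.9))
})

test_that("cross-correlation recovers constructed shifts to one sample", {
  set.seed(2)
  fs <- 20
  p <- as.numeric(stats::filter(rnorm(4000), rep(1, 10), sides = 1))
  p[is.na(p)] <- 0
  # movement is photometry shifted later by 0.5 s
  m <- c(rep(0, 10), p[1:(length(p) - 10)])
  lr <- crosscorr_lag(p, m, fs)
  expect_lte(abs(lr$lag_s - (-0.5)), 1 / fs)
  expect_equal(crosscorr_lag(p, p, fs)$lag_s, 0)
  expect_true(is.na(crosscorr_lag(rep(1, 100), p[1:100], fs)$lag_s))

  # shifts of 1..40 samples at high SNR are exact to one sample
  for (sh in c(1, 7, 40)) {
    m2 <- c(rep(0, sh), p[1:(length(p) - sh)]) + 0.01 * rnorm(length(p))
    expect_lte(abs(crosscorr_lag(p, m2, fs)$lag_s + sh / fs), 1 / fs)
  }
})

test_that("the 1.5 IQR rule flags a planted outlier subject", {
  flags <- iqr_outliers(c(0, 0, 0, 10))
  expect_equal(flags, c(FALSE, FALSE, FALSE, TRUE))
  expect_false(any(iqr_outliers(c(1, 2, 3, 4))))
})

test_that("mixed models favor movement over behavior labels on movement-driven data", {
  aics <- cached("lmm_aics", {
    d <- do.call(rbind, lapply(1:3, function(subj) {
      ch <- session_chain("behavior", seed = 300 + subj,
                          move_gain = exp(c(-0.2, 0, 0.2)[subj]))
      lab <- labels_from_likelihoods(ch$session$behavior$likelihoods, ch$fs)
      lab <- lab[(60 * ch$fs + 1):length(lab)]
      data.frame(y = ch$photometry$signal, mov = ch$movement$values,
                 beh = lab, subj = subj)
    }))
    suppressWarnings(
      suppressMessages(lmm_aic_trio(d$y, d$mov, d$beh, d$subj)))
  })
  expect_lt(aics$aic["model3"], aics$aic["model1"])
  expect_lt(aics$aic["model2"], aics$aic["model1"])
  # behavior adds little once movement is in the model
  expect_lt(abs(aics$aic["model2"] - aics$aic["model3"]),
            0.05 * (aics$aic["model1"] - aics$aic["model3"]))
  # determinism: identical data give identical AICs
  d0 <- data.frame(y = rep(rnorm(50), 2), mov = rep(rnorm(50), 2),
                   beh = factor(rep(c("a", "b"), 50)),
                   subj = rep(1:2, each = 50))
  a1 <- suppressWarnings(suppressMessages(
    lmm_aic_trio(d0$y, d0$mov, d0$beh, d0$subj)))$aic
  a2 <- suppressWarnings(suppressMessages(
    lmm_aic_trio(d0$y, d0$mov, d0$beh, d0$subj)))$aic
  expect_identical(a1, a2)
})

test_that("glucose preprocessing interpolates, smooths and differentiates", {
  # linear ramp: derivative equals the slope everywhere
  g <- data.frame(time_s = seq(0, 1000, 10), mM = 5 + 0.002 * seq(0, 1000, 10))
  gp <- glucose_preprocess(g, fs_target = 1)
  mid <- 350:650  # full 10-min smoothing windows only
  expect_equal(gp$derivative[mid], rep(0.002, length(mid)), tolerance = 1e-9)

  gc <- glucose_preprocess(data.frame(time_s = c(0, 500, 1000),
                                      mM = c(6, 6, 6)), 1)
  expect_equal(gc$derivative, rep(0, length(gc$derivative)))

  # logistic rise: derivative peaks near the inflection
  ts <- seq(0, 3600, 10)
  gl <- data.frame(time_s = ts, mM = 5 + 3 * stats::plogis((ts - 1800) / 150))
  gpl <- glucose_preprocess(gl, 1)
  expect_lt(abs(gpl$time_s[which.max(gpl$derivative)] - 1800), 30)

  # missing samples are interpolated before resampling
  gm <- g
  gm$mM[20:25] <- NA
  gpm <- glucose_preprocess(gm, 1)
  expect_true(all(is.finite(gpm$glucose)))
  expect_error(glucose_preprocess(data.frame(time_s = 1, mM = 5), 1),
               "at least 2")
})

test_that("per-IMF regression recovers constructed weights", {
  set.seed(5)
  n <- 3000
  mov <- rnorm(n)
  der <- rnorm(n)
  fake <- structure(list(imfs = rbind(2 * zscore(mov) + 0.05 * rnorm(n),
                                      rnorm(n)),
                         fs = 1, char_freq = c(0.05, 0.01)),
                    class = "imf_set")
  fit <- imf_multiplex_fit(fake, der, mov)
  expect_equal(fit$beta_movement[1], 2, tolerance = 0.01)
  expect_equal(fit$beta_glucose[1], 0, tolerance = 0.05)
  # independent IMF: both weights within 3 SE of zero
  expect_lt(abs(fit$beta_movement[2]), 3 * fit$se_movement[2])
  expect_lt(abs(fit$beta_glucose[2]), 3 * fit$se_glucose[2])
  expect_false(attr(fit, "collinear"))
  expect_warning(imf_multiplex_fit(fake, mov + 1e-4 * rnorm(n), mov),
                 "collinear")
})

test_that("multiplexed sessions separate movement and glucose by band", {
  res <- cached("multiplex_one", {
    ch <- session_chain("multiplex", seed = 4)
    is_ <- sift(ch$photometry$signal, ch$fs)
    gp <- glucose_preprocess(ch$session$glucose, ch$fs,
                             t_grid = ch$session$time[
                               (60 * ch$fs + 1):length(ch$session$time)])
    fit <- imf_multiplex_fit(is_, gp$derivative, ch$movement$values)
    bin_multiplex_weights(fit)
  })
  hi <- res[res$band == "high", ]
  lo <- res[res$band == "low", ]
  expect_gt(hi$beta_movement, 10 * abs(hi$beta_glucose))
  expect_lt(lo$beta_glucose, 0)
  expect_gt(abs(lo$beta_glucose), 10 * abs(lo$beta_movement))
})

test_that("glucose-percentile interaction distinguishes null from scaled coupling", {
  ch <- cached("chain_interaction", session_chain("movement", seed = 401,
                                                  fs = 5))
  gp <- glucose_preprocess(ch$session$glucose, ch$fs,
                           t_grid = ch$session$time[
                             (60 * ch$fs + 1):length(ch$session$time)])
  null_int <- percentile_interaction(ch$photometry$signal,
                                     ch$movement$values, gp$smoothed)
  expect_false(null_int$degenerate)
  expect_lt(abs(null_int$interaction), 0.01)

  # gain proportional to percentile gives a positive interaction
  pct <- 100 * (rank(gp$smoothed) - 0.5) / length(gp$smoothed)
  y <- rnorm(length(pct)) + (0.5 + 0.01 * pct) * ch$movement$values
  pos <- percentile_interaction(y, ch$movement$values, gp$smoothed)
  expect_lt(abs(pos$interaction - 0.01), 0.002)

  deg <- percentile_interaction(y, rep(1, length(y)), gp$smoothed)
  expect_true(deg$degenerate)
})

test_that("drop-one contributions isolate the informative feature", {
  set.seed(6)
  n <- 3000
  mov <- rnorm(n)
  X <- cbind(movement = mov, pupil = rnorm(n), ocular = rnorm(n))
  y <- mov + 0.05 * rnorm(n)
  pd <- pls_drop_one(X, y)
  expect_true(pd$defined)
  expect_equal(sum(pd$contributions), 100, tolerance = 1e-6)
  expect_gt(pd$contributions["movement"], 90)

  # permutation equivariance in feature order
  pd2 <- pls_drop_one(X[, c(3, 1, 2)], y)
  expect_equal(pd2$contributions[colnames(X)], pd$contributions,
               tolerance = 1e-6)

  # three identical features split evenly
  f <- rnorm(n)
  pd3 <- pls_drop_one(cbind(a = f, b = f, c = f), f + 0.1 * rnorm(n))
  expect_equal(unname(pd3$contributions), rep(100 / 3, 3), tolerance = 1e-6)

  # an uninformative target yields undefined contributions
  pd4 <- pls_drop_one(X, rnorm(n))
  expect_false(pd4$defined)
  expect_true(all(is.na(pd4$contributions)))
})

test_that("circular regression respects the wrap and recovers band phases", {
  set.seed(7)
  cf <- 10^stats::runif(80, -3, -1)
  # constant phase fits a constant curve
  cr0 <- circular_regression(cf, rep(pi / 2, 80))
  expect_true(all(abs(circ_diff(cr0$phase, pi / 2)) < 0.05))

  # phases wrapping through 0/2pi stay continuous
  phw <- (0.1 * rnorm(80)) %% (2 * pi)  # cluster straddling the wrap
  crw <- circular_regression(cf, phw)
  expect_true(all(abs(circ_diff(crw$phase, 0)) < 0.2))

  # band-dependent phase: pi/2 above 1e-2 Hz, 3pi/2 below
  ph <- ifelse(cf > 1e-2, pi / 2, 3 * pi / 2) + 0.1 * rnorm(80)
  cr <- circular_regression(cf, ph)
  expect_equal(nrow(cr), 7)
  hi <- cr$freq_hz > 2e-2
  lo <- cr$freq_hz < 5e-3
  expect_true(all(abs(circ_diff(cr$phase[hi], pi / 2)) < 0.3))
  expect_true(all(abs(circ_diff(cr$phase[lo], 3 * pi / 2)) < 0.3))
})
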