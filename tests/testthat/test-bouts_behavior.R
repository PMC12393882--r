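test_that("bout onsets require four quiet seconds then a zero crossing", {
  fs <- 20
  # 10 s below zero, then a step above: exactly one bout at the step
  x <- c(rep(-0.5, 10 * fs), rep(1, 5 * fs))
  b <- detect_bouts(x, fs, smooth_samples = 1)
  expect_equal(nrow(b), 1)
  expect_equal(b$onset, 10 * fs + 1)

  # only 3 s of quiescence: no bout
  x2 <- c(rep(0.2, 5 * fs), rep(-0.5, 3 * fs), rep(1, 3 * fs))
  expect_equal(nrow(detect_bouts(x2, fs, smooth_samples = 1)), 0)
})

test_that("bout detection is translation equivariant", {
  ch <- cached("chain_bouts", session_chain("bouts", seed = 2))
  b <- detect_bouts(ch$movement)
  shift <- 100L
  xs <- c(ch$movement$values[-seq_len(shift)],
          rep(-0.5, shift))  # shift left, pad quiet tail
  bs <- detect_bouts(xs, ch$fs)
  common <- intersect(b$onset - shift, bs$onset)
  expect_gt(length(common) / nrow(b), 0.9)
})

test_that("detector recovers generated bouts and k-means separates sizes", {
  ch <- cached("chain_bouts", session_chain("bouts", seed = 2))
  b <- detect_bouts(ch$movement)
  truth <- truth_onsets_trimmed(ch$session)
  off <- vapply(truth, function(o) min(abs(b$onset_s - o)), numeric(1))
  expect_gt(mean(off <= 0.5), 0.9)

  cb <- cluster_bouts(b, ch$movement)
  m <- vapply(cb$onset_s, function(o) which.min(abs(truth - o)), integer(1))
  ok <- abs(truth[m] - cb$onset_s) <= 0.5
  truth_lab <- ch$session$truth$bout_cluster[
    ch$session$truth$bout_onsets_s - 60 > 4]
  expect_gt(mean(cb$cluster[ok] == truth_lab[m[ok]]), 0.95)
})

test_that("bout clustering handles degenerate and boundary cases", {
  fs <- 20
  x <- rep(-0.5, 60 * fs)
  for (o in c(10, 25, 40)) x[(o * fs):(o * fs + 2 * fs)] <- 1  # identical bouts
  b <- detect_bouts(x, fs, smooth_samples = 1)
  expect_equal(nrow(b), 3)
  expect_warning(cb <- cluster_bouts(b, x, k = 2), "degenerate")
  expect_true(all(cb$cluster == "small"))

  expect_equal(unique(cluster_bouts(b, x, k = 1)$cluster), "small")
  b1 <- b[1, , drop = FALSE]
  class(b1) <- class(b); attr(b1, "fs") <- fs
  expect_warning(c1 <- cluster_bouts(b1, x, k = 2), "fewer bouts")
  expect_equal(c1$cluster, "small")

  # cluster labels are invariant to bout order permutation
  bp <- b[c(2, 3, 1), ]
  class(bp) <- class(b); attr(bp, "fs") <- fs
  amp <- c(1, 3, 1)
  x2 <- rep(-0.5, 60 * fs)
  for (i in 1:3) x2[(c(10, 25, 40)[i] * fs):(c(10, 25, 40)[i] * fs + 2 * fs)] <- amp[i]
  l1 <- cluster_bouts(b, x2, k = 2)
  l2 <- cluster_bouts(bp, x2, k = 2)
  expect_equal(l1$cluster[match(l2$onset, l1$onset)], l2$cluster)
})

test_that("bout-aligned baselining re-expresses segments in baseline units", {
  fs <- 20
  x <- rep(0, 60 * fs)
  set.seed(3)
  x[] <- rnorm(length(x))          # baseline SD 1 by construction
  onset <- 30 * fs
  x[onset:length(x)] <- x[onset:length(x)] + 1  # +1 SD step at onset
  seg <- align_and_baseline(x, onset, fs)
  ts <- attr(seg, "time_s")
  expect_equal(mean(seg[1, ts > 0]), 1, tolerance = 0.2)
  expect_equal(mean(seg[1, ts >= -3 & ts <= -1]), 0, tolerance = 0.2)

  # constant trace maps to all zeros
  segc <- align_and_baseline(rep(2, 60 * fs), onset, fs)
  expect_true(all(segc == 0))

  # bouts too close to the edge are dropped and counted
  seg2 <- align_and_baseline(x, c(5L, onset), fs)
  expect_equal(nrow(seg2), 1)
  expect_equal(attr(seg2, "n_dropped"), 1)
})

test_that("label smoothing takes the max-likelihood class with tie rules", {
  lik <- matrix(0, 10, 5)
  lik[, 2] <- 1
  lab <- labels_from_likelihoods(lik, fs = 1, smooth_s = 4)
  expect_true(all(lab == "running"))

  # a 2-frame blip inside a long run is absorbed by the 4 s filter;
  # the expected labels come from a hand argmax of the smoothed columns
  lik2 <- matrix(0, 40, 5)
  lik2[, 1] <- 1
  lik2[20:21, ] <- 0
  lik2[20:21, 3] <- 1
  sm <- apply(lik2, 2, movemux:::moving_average, k = 4)
  hand <- apply(sm, 1, which.max)
  lab2 <- labels_from_likelihoods(lik2, fs = 1, smooth_s = 4)
  expect_equal(as.integer(lab2), hand)
  expect_true(all(lab2 == "resting"))

  # exact tie at frame 1 resolves to the first class in canonical order
  lik3 <- matrix(0.5, 2, 5)
  lik3[, 3:5] <- 0
  lik3 <- lik3 / rowSums(lik3)
  lab3 <- labels_from_likelihoods(lik3, fs = 1, smooth_s = 1)
  expect_equal(as.character(lab3[1]), "resting")

  expect_error(labels_from_likelihoods(matrix(0.3, 5, 5), 1), "sum to 1")
})

test_that("transition matrices are row-stochastic counts of label changes", {
  lv <- c("resting", "running", "grooming", "chewing", "sniffing")
  lab <- factor(c("resting", "running", "resting", "running"), levels = lv)
  P <- transition_matrix(lab)
  expect_equal(P["resting", "running"], 1)
  expect_equal(P["running", "resting"], 1)
  rs <- rowSums(P)
  expect_true(all(rs[rs > 0] == 1))

  Pc <- transition_matrix(factor(rep("resting", 10), levels = lv))
  expect_true(all(Pc == 0))
  expect_true("resting" %in% attr(Pc, "undefined_rows"))

  # Markov-generated labels recover the generating matrix
  set.seed(9)
  Pgen <- matrix(0.02, 5, 5); diag(Pgen) <- 0.92
  n <- 1e5
  lab2 <- integer(n); lab2[1] <- 1L
  cum <- t(apply(Pgen, 1, cumsum))
  u <- stats::runif(n)
  for (i in 2:n) lab2[i] <- findInterval(u[i], cum[lab2[i - 1], ]) + 1L
  Ph <- transition_matrix(factor(lv[lab2], levels = lv))
  # conditioned on leaving, every exit is uniform over the other classes
  expect_lt(max(abs(Ph - 0.25 * (1 - diag(5)))), 0.05)
})

test_that("transition-aligned averages match a direct per-window mean", {
  ch <- cached("chain_default", session_chain(seed = 3))
  lab <- labels_from_likelihoods(ch$session$behavior$likelihoods, ch$fs)
  lab <- lab[(60 * ch$fs + 1):length(lab)]
  tr <- align_to_transitions(ch$photometry$signal, lab, ch$fs, top_n = 3)
  expect_gt(length(tr), 0)
  ty <- names(tr)[1]
  # oracle: direct mean over the same windows
  n <- length(lab)
  idx <- which(lab[-1] != lab[-n]) + 1L
  w <- 4 * ch$fs
  idx <- idx[idx - w >= 1 & idx + w <= n]
  tt <- paste0(lab[idx - 1], "->", lab[idx])
  ii <- idx[tt == ty]
  oracle <- colMeans(t(vapply(ii, function(i)
    ch$photometry$signal[(i - w):(i + w)], numeric(2 * w + 1))))
  expect_equal(tr[[ty]]$mean, oracle, tolerance = 1e-12)
  expect_equal(tr[[ty]]$n, length(ii))
})

test_that("per-class means follow the labels exactly and flag absent classes", {
  lv <- c("resting", "running", "grooming", "chewing", "sniffing")
  lab <- factor(rep(c("resting", "running"), each = 50), levels = lv)
  trace <- ifelse(lab == "running", 2, -1)
  m <- behavior_means(trace, lab)
  expect_equal(unname(m[c("resting", "running")]), c(-1, 2))
  expect_true(is.na(m["grooming"]))
})

test_that("class-modulated sessions show matched photometry and movement means", {
  ch <- cached("chain_default", session_chain(seed = 3))
  lab <- labels_from_likelihoods(ch$session$behavior$likelihoods, ch$fs)
  lab <- lab[(60 * ch$fs + 1):length(lab)]
  mp <- behavior_means(ch$photometry$signal, lab)
  mm <- behavior_means(ch$movement$values, lab)
  ok <- is.finite(mp) & is.finite(mm)
  expect_gt(stats::cor(mp[ok], mm[ok]), 0.95)
})
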