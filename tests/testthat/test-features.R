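test_that("band power localizes tones in the published band edges", {
  # 10 Hz tone: nearly all 1-30 Hz power lands in alpha, ratio 1
  rec <- sine_recording(rep(10, 19), fs = 250, duration_s = 16)
  bp <- band_power(rec)
  total <- colSums(bp$per_channel)
  expect_true(all(bp$per_channel["alpha", ] / total >= 0.95))
  expect_equal(unname(bp$ratio[["alpha"]]), 1, tolerance = 1e-9)
  # 2 Hz (amp 1) + 20 Hz (amp 2): beta/delta power ratio ~ 4 (Parseval)
  t <- seq_len(16 * 250) / 250
  x <- sin(2 * pi * 2 * t) + 2 * sin(2 * pi * 20 * t)
  rec2 <- eeg_recording(matrix(rep(x, 19), 19, byrow = TRUE), fs = 250)
  bp2 <- band_power(rec2)
  expect_equal(unname(bp2$ft[["beta"]] / bp2$ft[["delta"]]), 4,
               tolerance = 0.05)
  expect_error(band_power(sine_recording(rep(10, 2), duration_s = 4)),
               "degenerate")
})

test_that("band power respects Parseval within leakage tolerance", {
  set.seed(21)
  # band-limited input: sum of in-band tones
  t <- seq_len(16 * 250) / 250
  x <- sin(2 * pi * 3 * t) + sin(2 * pi * 10 * t) + sin(2 * pi * 25 * t)
  rec <- eeg_recording(rbind(x, x), fs = 250,
                       channel_labels = c("Fp1", "O1"))
  bp <- band_power(rec, region_scheme(ft = "Fp1", cpo = "O1"))
  band_total <- sum(bp$per_channel[, 1])
  # total signal power on the same segment/window convention
  L <- 8 * 250
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  starts <- seq(1, length(x) - L + 1, by = L / 2)
  freqs <- (seq_len(L) - 1) * 250 / L
  one_sided <- freqs > 0 & freqs <= 125
  full <- mean(vapply(starts, function(s)
    sum(Mod(fft(x[s:(s + L - 1)] * w))[one_sided]^2), numeric(1)))
  expect_lte(band_total, full * 1.0001)
  expect_gt(band_total, 0.9 * full)
})

test_that("Hjorth parameters match analytic and Monte-Carlo references", {
  # pure tone, 1000 samples per cycle: mobility -> omega, complexity -> 1
  x <- sin(2 * pi * seq(0, 10, length.out = 10001))
  h <- hjorth(x)
  expect_equal(unname(h["mobility"]), 2 * pi / 1000, tolerance = 0.02)
  expect_equal(unname(h["complexity"]), 1, tolerance = 0.02)
  # white noise: activity ~ sigma^2
  set.seed(22)
  hn <- hjorth(rnorm(1e5, sd = 3))
  expect_equal(unname(hn["activity"]), 9, tolerance = 0.05 * 9)
  expect_error(hjorth(rep(1, 100)), "zero-variance")
  expect_error(hjorth(c(1, 2)), "3 samples")
  # complexity >= 1 - eps across signal types
  set.seed(23)
  for (x in list(rnorm(5000), cumsum(rnorm(5000)),
                 sin(2 * pi * 7 * seq_len(5000) / 250)))
    expect_gte(unname(hjorth(x)["complexity"]), 1 - 0.02)
})

test_that("dyadic wavelet decomposition behaves like a filter bank", {
  expect_error(dwt_dyadic(rnorm(256), template = "nope"), "config")
  # haar details of a constant signal vanish under periodic extension
  d <- dwt_dyadic(rep(3, 256), template = "haar")
  for (lev in 1:5) expect_lt(max(abs(d$details[[lev]])), 1e-10)
  # each level halves the length
  d2 <- dwt_dyadic(rnorm(320), template = "db4")
  expect_equal(lengths(d2$details), c(160, 80, 40, 20, 10))
  # a slow tone's energy concentrates in the coarse subbands
  x <- sin(2 * pi * 2 * seq_len(2000) / 250)     # 2 Hz at 250 Hz
  d3 <- dwt_dyadic(x, template = "db4")
  e <- vapply(d3$details, function(v) sum(v^2), numeric(1))
  expect_gt(sum(e[4:5]), sum(e[1:2]))
})

test_that("time-frequency features have the documented 285-length layout", {
  set.seed(24)
  rec <- eeg_recording(matrix(rnorm(19 * 16 * 250), 19), fs = 250)
  tf <- timefreq_features(rec)
  expect_length(tf, 285)
  expect_true(all(is.finite(tf)))
  # 16 s with 8 s windows at 50% overlap -> 3 windows
  seg <- sinkindex:::.segment_starts(16 * 250, 250, 8, 0.5)
  expect_length(seg$starts, 3)
  # permuting channels permutes the per-channel feature blocks
  perm <- sample(19)
  rec_p <- eeg_recording(rec$data[perm, ], fs = 250,
                         channel_labels = rec$channel_labels[perm])
  tf_p <- timefreq_features(rec_p)
  for (ch in rec$channel_labels) {
    blk <- grep(paste0("^", ch, "\\."), names(tf))
    blk_p <- grep(paste0("^", ch, "\\."), names(tf_p))
    expect_equal(unname(tf[blk]), unname(tf_p[blk_p]), tolerance = 1e-10)
  }
})

test_that("PCA reduction is train-only, orthonormal and variance-ordered", {
  set.seed(25)
  train <- matrix(rnorm(40 * 20), 40)
  test <- matrix(rnorm(5 * 20), 5)
  red <- pca_reduce(train, test, k = 5)
  expect_equal(ncol(red$train), 5)
  expect_equal(ncol(red$test), 5)
  expect_equal(crossprod(red$rotation), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # projected training covariance is diagonal with decreasing variance
  cv <- cov(red$train)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_true(all(diff(diag(cv)) <= 1e-8))
  # exact low-rank data reconstructs perfectly with matching k
  base <- matrix(rnorm(30 * 2), 30) %*% matrix(rnorm(2 * 10), 2)
  red2 <- pca_reduce(base, k = 2)
  recon <- red2$train %*% t(red2$rotation) +
    matrix(red2$center, 30, 10, byrow = TRUE)
  expect_equal(recon, base, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(pca_reduce(train, test, k = 50), "config")
})
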