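test_that("window segmentation follows the floor convention", {
  rec <- eeg_recording(matrix(rnorm(2 * 2500), 2), fs = 250)
  win <- segment_windows(rec, T_ms = 125)
  expect_equal(attr(win, "window_len"), 31)
  expect_equal(nrow(win), 80)
  expect_equal(win$start[1], 1)
  expect_equal(win$end[80], 80 * 31)
  # exactly one window at 31 samples; error below that
  one <- eeg_recording(matrix(rnorm(2 * 31), 2), fs = 250)
  expect_equal(nrow(segment_windows(one, 125)), 1)
  short <- eeg_recording(matrix(rnorm(2 * 30), 2), fs = 250)
  expect_error(segment_windows(short, 125), "degenerate")
})

test_that("noise-free least squares recovers the generating matrix exactly", {
  for (N in 3:6) {
    A0 <- random_stable_A(N, seed = N)
    W <- lti_trajectory(A0, n = 50, seed = N + 10)
    A <- fit_transition_matrix(W, ridge = 0)
    expect_lt(norm(A - A0, "F"), 1e-8)
    # brute-force normal-equations oracle agrees with the solve path
    X <- W[, -ncol(W)]; Y <- W[, -1]
    A_oracle <- Y %*% t(X) %*% solve(X %*% t(X))
    expect_lt(norm(A - A_oracle, "F"), 1e-8)
  }
})

test_that("noisy least squares is consistent at large sample size", {
  set.seed(42)
  N <- 19
  # well-excited system: isotropic stationary covariance, every mode
  # persistently driven, so the least-squares error is O(N/sqrt(n))
  A0 <- scaled_orthogonal_A(N, seed = 42)
  n <- 10000
  x <- rnorm(N)
  W <- matrix(0, N, n)
  for (t in seq_len(n)) {
    x <- as.numeric(A0 %*% x) + rnorm(N, sd = 0.1)
    W[, t] <- x
  }
  A <- fit_transition_matrix(W)
  expect_lt(norm(A - A0, "F"), 0.05)
})

test_that("degenerate windows are rejected or flagged", {
  expect_error(fit_transition_matrix(matrix(0, 3, 10)), "singular")
  # fewer regression pairs than channels with ridge 0: flagged minimum-norm
  W <- matrix(rnorm(5 * 4), 5, 4)
  A <- fit_transition_matrix(W, ridge = 0)
  expect_match(attr(A, "flag"), "minimum-norm|pseudo-inverse")
})

test_that("fit_dnm produces one matrix per window with shape invariants", {
  net <- planted_network(N = 4, noise_sd = 1, fs = 250, seed = 3,
                         channel_labels = c("Fp1", "F3", "C3", "O1"))
  rec <- simulate_recording(net, duration_s = 4)
  fit <- fit_dnm(rec, T_ms = 125)
  expect_s3_class(fit, "dnm")
  expect_equal(fit$n_windows, floor(1000 / 31))
  expect_true(all(fit$valid))
  expect_true(all(vapply(fit$A_seq, function(A) all(dim(A) == c(4, 4)),
                         logical(1))))
  A <- coef(fit)
  expect_equal(dim(A), c(4, 4, fit$n_windows))
  # reversed input keeps the shape contract
  rev_rec <- eeg_recording(rec$data[, rev(seq_len(ncol(rec$data)))],
                           fs = rec$fs, channel_labels = rec$channel_labels)
  fit_rev <- fit_dnm(rev_rec, T_ms = 125)
  expect_equal(fit_rev$n_windows, fit$n_windows)
})

test_that("a flatline stretch is skipped, logged and excluded downstream", {
  set.seed(8)
  data <- matrix(rnorm(3 * 310), 3)
  data[, 1:62] <- 0                     # first two windows are all-zero
  rec <- eeg_recording(data, fs = 250, channel_labels = c("Fp1", "Cz", "O1"))
  fit <- fit_dnm(rec, T_ms = 125)
  expect_equal(sum(!fit$valid), 2)
  expect_match(fit$cond_flags[1], "zero")
  sm <- sink_map(fit)
  expect_true(all(is.na(sm$si[, 1:2])))
  expect_false(anyNA(sm$time_avg_si))
})

test_that("a piecewise-constant switch is localized by the window fits", {
  N <- 4
  A1 <- random_stable_A(N, seed = 21)
  A2 <- random_stable_A(N, seed = 22)
  net <- planted_network(N = N, noise_sd = 0.2, fs = 250, seed = 23,
                         A_schedule = list(list(A = A1, duration_s = 4),
                                           list(A = A2, duration_s = 4)),
                         channel_labels = c("Fp1", "F3", "C3", "O1"))
  rec <- simulate_recording(net, duration_s = 8)
  fit <- fit_dnm(rec, T_ms = 125)
  mid <- floor(fit$n_windows / 2)
  d <- function(k, A) norm(fit$A_seq[[k]] - A, "F")
  first <- seq_len(mid - 1); second <- (mid + 2):fit$n_windows
  expect_lt(mean(vapply(first, d, numeric(1), A = A1)),
            mean(vapply(first, d, numeric(1), A = A2)))
  expect_lt(mean(vapply(second, d, numeric(1), A = A2)),
            mean(vapply(second, d, numeric(1), A = A1)))
})

test_that("fits are deterministic and scale-equivariant", {
  net <- planted_network(N = 5, noise_sd = 0.5, fs = 250, seed = 9)
  rec <- simulate_recording(net, duration_s = 4)
  f1 <- fit_dnm(rec); f2 <- fit_dnm(rec)
  expect_identical(f1$A_seq, f2$A_seq)
  # common scalar rescaling of all channels leaves every A unchanged
  rec2 <- eeg_recording(rec$data * 7.3, fs = rec$fs,
                        channel_labels = rec$channel_labels)
  f3 <- fit_dnm(rec2, ridge = 0)
  f1r <- fit_dnm(rec, ridge = 0)
  for (k in seq_len(f1r$n_windows))
    expect_lt(norm(f1r$A_seq[[k]] - f3$A_seq[[k]], "F"), 1e-8)
})

test_that("dnm methods: predict aligns with residuals and simulate reproduces", {
  net <- planted_network(N = 4, noise_sd = 0.5, fs = 250, seed = 31,
                         channel_labels = c("Fp1", "F3", "C3", "O1"))
  rec <- simulate_recording(net, duration_s = 2)
  fit <- fit_dnm(rec)
  pred <- predict(fit, rec)
  res <- residuals(fit, rec)
  idx <- which(!is.na(pred[1, ]))
  expect_equal(pred[, idx] + res[, idx], rec$data[, idx],
               tolerance = 1e-12, ignore_attr = TRUE)
  s1 <- simulate(fit, seed = 1)
  s2 <- simulate(fit, seed = 1)
  expect_identical(s1$data, s2$data)
})
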