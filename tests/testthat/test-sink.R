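test_that("row and column norms match a brute-force elementwise oracle", {
  expect_equal(row_col_norms(diag(4)),
               list(row_sizes = rep(1, 4), col_sizes = rep(1, 4)))
  A <- rbind(c(0, 0), c(0.9, 0))
  expect_equal(row_col_norms(A),
               list(row_sizes = c(0, 0.9), col_sizes = c(0.9, 0)))
  set.seed(3)
  B <- matrix(rnorm(25), 5)
  oracle_row <- vapply(1:5, function(i)
    sqrt(sum(vapply(1:5, function(j) B[i, j]^2, numeric(1)))), numeric(1))
  oracle_col <- vapply(1:5, function(j)
    sqrt(sum(vapply(1:5, function(i) B[i, j]^2, numeric(1)))), numeric(1))
  ns <- row_col_norms(B)
  expect_equal(ns$row_sizes, oracle_row, tolerance = 1e-12)
  expect_equal(ns$col_sizes, oracle_col, tolerance = 1e-12)
  expect_error(row_col_norms(matrix(1, 2, 3)), "square")
})

test_that("normalized ranks hit the {1/N..1} grid with stable tie-breaks", {
  expect_equal(normalized_ranks(c(3, 1, 2)), c(1, 1 / 3, 2 / 3))
  expect_equal(normalized_ranks(rep(2, 4)), (1:4) / 4)
  set.seed(4)
  for (i in 1:20) {
    v <- rnorm(sample(2:30, 1))
    r <- normalized_ranks(v)
    N <- length(v)
    expect_setequal(round(r * N), 1:N)
    # sort-based oracle: ranks are monotone in the input ordering
    expect_equal(order(r), order(v))
  }
  expect_error(normalized_ranks(c(1, NaN)), "validation")
})

test_that("sink index reproduces the closed-form reference points", {
  si <- sink_index_of_matrix(rbind(c(0, 0), c(0.9, 0)))
  expect_equal(unname(si[2]), sqrt(2), tolerance = 1e-5)   # ideal sink
  expect_equal(unname(si[1]), sqrt(2) - sqrt(0.5), tolerance = 1e-5)
  # a channel at rank pair (10/19, 10/19) scores sqrt(2) * 10/19
  N <- 19
  r <- 10 / 19
  expect_equal(sqrt(2) - sqrt((r - 1)^2 + (r - 1 / N)^2), 0.74432,
               tolerance = 1e-5)
})

test_that("a 4-node network with one sink and one source orders as expected", {
  # node 2: near-zero column, large row; node 3: the reverse
  A <- rbind(c(0.3, 0.01, 0.8, 0.1),
             c(0.9, 0.30, 0.9, 0.8),
             c(0.1, 0.01, 0.3, 0.0),
             c(0.2, 0.02, 0.7, 0.3))
  si <- sink_index_of_matrix(A)
  expect_equal(which.max(si), 2)
  expect_equal(which.min(si), 3)
})

test_that("sink index bounds hold on the full rank grid", {
  rng <- sink_index_range(19)
  expect_equal(rng$max, sqrt(2), tolerance = 1e-12)
  expect_equal(rng$min, sqrt(2) / 19, tolerance = 1e-12)
  expect_true(all(rng$grid$si >= rng$min & rng$grid$si <= rng$max))
  # configurable constant shifts the whole range
  rng2 <- sink_index_range(19, eq2_constant = 2)
  expect_equal(rng2$max, 2, tolerance = 1e-12)
})

test_that("transposition swaps sinks and sources", {
  set.seed(6)
  for (i in 1:10) {
    A <- matrix(rnorm(36), 6)
    siA <- sink_index_of_matrix(A)
    siT <- sink_index_of_matrix(t(A))
    nsA <- row_col_norms(A)
    # transpose swaps the rank pair of every channel
    expect_equal(normalized_ranks(nsA$row_sizes),
                 normalized_ranks(row_col_norms(t(A))$col_sizes))
    expect_equal(normalized_ranks(nsA$col_sizes),
                 normalized_ranks(row_col_norms(t(A))$row_sizes))
    # a pure sink becomes a pure source
    B <- matrix(0, 5, 5); diag(B) <- 0.1
    B[2, ] <- 0.9; B[2, 2] <- 0.1; B[, 2] <- c(0, 0.1, 0, 0, 0)
    expect_equal(which.max(sink_index_of_matrix(B)), 2)
    expect_equal(which.min(sink_index_of_matrix(t(B))), 2)
  }
})

test_that("sink maps respect per-window structure and channel equivariance", {
  net <- planted_network(N = 5, noise_sd = 0.5, fs = 250, seed = 14)
  rec <- simulate_recording(net, duration_s = 4)
  fit <- fit_dnm(rec)
  sm <- sink_map(fit)
  # each window's si column equals the single-matrix computation
  for (k in c(1, 5, fit$n_windows))
    expect_equal(unname(sm$si[, k]),
                 unname(sink_index_of_matrix(fit$A_seq[[k]])))
  # identical A in every window: identical columns, average = any column
  fit2 <- fit
  for (k in seq_len(fit2$n_windows)) fit2$A_seq[[k]] <- fit$A_seq[[1]]
  sm2 <- sink_map(fit2)
  expect_true(all(apply(sm2$si, 1, function(r) max(r) - min(r)) < 1e-12))
  expect_equal(sm2$time_avg_si, sm2$si[, 1])
  # permuting channels permutes rows of the map identically
  perm <- c(3, 1, 5, 2, 4)
  rec_p <- eeg_recording(rec$data[perm, ], fs = rec$fs,
                         channel_labels = rec$channel_labels[perm])
  sm_p <- sink_map(fit_dnm(rec_p))
  expect_equal(unname(sm_p$time_avg_si),
               unname(sm$time_avg_si[perm]), tolerance = 1e-8)
})

test_that("windows attain exactly one maximal row and column rank", {
  net <- planted_network(N = 7, noise_sd = 0.5, fs = 250, seed = 15)
  rec <- simulate_recording(net, duration_s = 2)
  sm <- sink_map(fit_dnm(rec))
  for (k in seq_len(ncol(sm$si))) {
    expect_equal(sum(sm$rr_rank[, k] == 1), 1)
    expect_equal(sum(sm$cr_rank[, k] == 1), 1)
  }
  # bounds on every entry
  N <- 7
  expect_true(all(sm$si >= sqrt(2) - sqrt(2) * (1 - 1 / N) - 1e-12))
  expect_true(all(sm$si <= sqrt(2) + 1e-12))
})

test_that("a sink planted only in the second half raises its late SI", {
  N <- 6
  A_plain <- make_planted_A(N, seed = 33)
  A_sink <- make_planted_A(N, sink_idx = 2, strength = 0.9, seed = 33)
  net <- planted_network(N = N, noise_sd = 0.3, fs = 250, seed = 34,
                         A_schedule = list(list(A = A_plain, duration_s = 6),
                                           list(A = A_sink, duration_s = 6)))
  rec <- simulate_recording(net, duration_s = 12)
  sm <- sink_map(fit_dnm(rec))
  mid <- floor(ncol(sm$si) / 2)
  expect_gt(mean(sm$si[2, (mid + 1):ncol(sm$si)]),
            mean(sm$si[2, 1:mid]))
})

test_that("subject markers average regions and form the FT/CPO ratio", {
  net <- planted_network(N = 19, noise_sd = 0.5, fs = 250, seed = 16)
  rec <- simulate_recording(net, duration_s = 4)
  sm <- sink_map(fit_dnm(rec))
  mk <- subject_marker(sm)
  sch <- region_scheme()
  expect_equal(mk$si_ft, mean(sm$time_avg_si[sch$ft]))
  expect_equal(mk$si_cpo, mean(sm$time_avg_si[sch$cpo]))
  expect_equal(mk$si_ratio, mk$si_ft / mk$si_cpo)
  # constant map gives ratio 1; a 2x FT elevation gives ratio 2
  sm_c <- sm
  sm_c$time_avg_si[] <- 0.9
  mk_c <- subject_marker(sm_c)
  expect_equal(mk_c$si_ratio, 1)
  sm_2 <- sm
  sm_2$time_avg_si[sch$ft] <- 1.2
  sm_2$time_avg_si[sch$cpo] <- 0.6
  expect_equal(subject_marker(sm_2)$si_ratio, 2)
  # incomplete scheme is rejected
  expect_error(subject_marker(sm, region_scheme(ft = "Fp1", cpo = "O1")),
               "misses")
})

test_that("the default region scheme matches the published 8/11 split", {
  sch <- region_scheme()
  expect_setequal(sch$ft, c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "T3", "T4"))
  expect_setequal(sch$cpo, c("O1", "T5", "O2", "T6", "Cz", "Pz", "P3",
                             "Fz", "P4", "C3", "C4"))
  expect_length(intersect(sch$ft, sch$cpo), 0)
  expect_setequal(c(sch$ft, sch$cpo), canonical_channels())
})
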