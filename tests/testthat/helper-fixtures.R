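# Shared fixtures, all generated in code.

# deterministic multichannel sine recording
sine_recording <- function(freqs, fs = 250, duration_s = 10, amp = 1,
                           n_channels = length(freqs)) {
  t <- seq_len(round(fs * duration_s)) / fs
  data <- t(vapply(rep_len(freqs, n_channels),
                   function(f) amp * sin(2 * pi * f * t), numeric(length(t))))
  eeg_recording(data, fs = fs)
}

# small stable random transition matrix
random_stable_A <- function(N, radius = 0.8, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(N * N), N, N)
  A * radius / max(Mod(eigen(A, only.values = TRUE)$values))
}

# scaled random rotation: every mode has |lambda| = radius, so noise-free
# trajectories neither decay (identifiability is preserved over long
# horizons) nor blow up, and the driven stationary covariance is isotropic
scaled_orthogonal_A <- function(N, radius = 0.975, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(N * N), N, N))) * radius
}

# noise-free trajectory x(t+1) = A x(t) from a random start
lti_trajectory <- function(A, n, seed = 1) {
  set.seed(seed)
  N <- nrow(A)
  x <- rnorm(N)
  out <- matrix(0, N, n)
  for (t in seq_len(n)) {
    out[, t] <- x
    x <- as.numeric(A %*% x)
  }
  out
}

# tiny BIDS-like cohort directory with a participants table
write_fixture_cohort <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(
    participant_id = c("sub-001", "sub-002", "sub-003"),
    Gender = c("F", "M", "M"),
    Age = c(57, 70, 67),
    Group = c("F", "A", "C"),
    MMSE = c(22, 14, 30))
  write.table(tab, file.path(dir, "participants.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  dir
}
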