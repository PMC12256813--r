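#' Segment a recording into non-overlapping model windows
#'
#' Splits the sample axis into contiguous, non-overlapping, half-open index
#' ranges of `T_ms` milliseconds; a trailing partial window is dropped.
#'
#' @param rec an [eeg_recording].
#' @param T_ms window duration in milliseconds (default 125).
#' @return data.frame with columns `start`, `end` (inclusive 1-based sample
#'   indices) and attribute `window_len` (samples per window).
#' @export
segment_windows <- function(rec, T_ms = 125) {
  stopifnot_recording(rec)
  L <- floor(T_ms * rec$fs / 1000)
  if (L < 2L)
    stop("window of ", T_ms, " ms holds fewer than 2 samples at fs = ",
         rec$fs, call. = FALSE)
  n <- n_samples(rec)
  k <- floor(n / L)
  if (k < 1L)
    stop("degenerate input: recording shorter than one ", T_ms,
         " ms window", call. = FALSE)
  starts <- (seq_len(k) - 1L) * L + 1L
  out <- data.frame(start = starts, end = starts + L - 1L)
  attr(out, "window_len") <- L
  out
}

#' Least-squares state-transition matrix for one window
#'
#' Fits the one-step linear model x(t+1) = A x(t) to the L-1 consecutive
#' sample pairs of a single window, minimizing the summed squared residual
#' over A. The normal equations are solved with an optional ridge term
#' added to the Gram matrix; with `ridge = 0` and a rank-deficient Gram
#' matrix the minimum-norm (pseudo-inverse) solution is returned and
#' flagged.
#'
#' @param window_data numeric matrix, channels x samples (L >= 2 columns).
#' @param ridge nonnegative ridge coefficient added as `ridge * I` to the
#'   Gram matrix. `NULL` (default) uses `1e-6 * mean(diag(Gram))`, a
#'   relative stabilizer that leaves well-conditioned fits essentially
#'   untouched; `0` is plain least squares.
#' @return N x N matrix `A` with attribute `flag` (`NA_character_` when the
#'   fit was clean, otherwise a short description).
#' @export
fit_transition_matrix <- function(window_data, ridge = NULL) {
  W <- as.matrix(window_data)
  N <- nrow(W); L <- ncol(W)
  if (L < 2L) stop("window has fewer than 2 samples", call. = FALSE)
  if (all(W == 0))
    stop("singular system: all-zero window", call. = FALSE)
  X <- W[, -L, drop = FALSE]          # x(t),   N x (L-1)
  Y <- W[, -1L, drop = FALSE]         # x(t+1), N x (L-1)
  G <- tcrossprod(X)                  # X X'
  if (is.null(ridge)) ridge <- 1e-6 * mean(diag(G))
  flag <- NA_character_
  if (L - 1L < N && ridge == 0) flag <- "underdetermined: minimum-norm solution"
  A <- NULL
  if (ridge > 0) {
    Gr <- G + diag(ridge, N)
    A <- tryCatch(t(solve(Gr, tcrossprod(X, Y))), error = function(e) NULL)
  } else {
    A <- tryCatch(t(solve(G, tcrossprod(X, Y))), error = function(e) NULL)
  }
  if (is.null(A)) {
    # rank-deficient Gram matrix: minimum-norm solution via pseudo-inverse
    A <- Y %*% pinv(X)
    flag <- "singular Gram matrix: pseudo-inverse solution"
  }
  dimnames(A) <- list(rownames(W), rownames(W))
  attr(A, "flag") <- flag
  A
}

# Moore-Penrose pseudo-inverse via SVD (tolerance as in MASS::ginv)
pinv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fit a linear time-varying dynamic network model
#'
#' Estimates one state-transition matrix per non-overlapping window of
#' `T_ms` milliseconds by least squares, producing the windowed sequence
#' that constitutes the subject's dynamic network model (DNM). A window
#' whose fit fails (for example an all-zero flatline segment) is skipped
#' and recorded, not fatal.
#'
#' @inheritParams segment_windows
#' @inheritParams fit_transition_matrix
#' @return Object of class `dnm`: list with `A_seq` (list of N x N
#'   matrices, temporal order), `valid` (logical per window), `cond_flags`
#'   (character per window), `window_len_samples`, `window_duration_ms`,
#'   `fs`, `channel_labels`, `n_windows`, `subject_id`.
#' @seealso [sink_map()] to derive sink indices, [coef.dnm()],
#'   [predict.dnm()], [simulate.dnm()].
#' @examples
#' rec <- simulate_recording(planted_network(N = 5, seed = 1), duration_s = 4)
#' fit <- fit_dnm(rec)
#' fit
#' @export
fit_dnm <- function(rec, T_ms = 125, ridge = NULL) {
  stopifnot_recording(rec)
  win <- segment_windows(rec, T_ms)
  L <- attr(win, "window_len")
  M <- nrow(win)
  A_seq <- vector("list", M)
  flags <- rep(NA_character_, M)
  valid <- rep(TRUE, M)
  for (k in seq_len(M)) {
    Wk <- rec$data[, win$start[k]:win$end[k], drop = FALSE]
    A <- tryCatch(fit_transition_matrix(Wk, ridge = ridge),
                  error = function(e) e)
    if (inherits(A, "error")) {
      valid[k] <- FALSE
      flags[k] <- conditionMessage(A)
      A_seq[k] <- list(NULL)
    } else {
      flags[k] <- attr(A, "flag")
      attr(A, "flag") <- NULL
      A_seq[[k]] <- A
    }
  }
  structure(
    list(A_seq = A_seq, valid = valid, cond_flags = flags,
         window_len_samples = L, window_duration_ms = T_ms,
         fs = rec$fs, channel_labels = rec$channel_labels,
         n_windows = M, subject_id = rec$subject_id),
    class = "dnm"
  )
}

#' @export
print.dnm <- function(x, ...) {
  cat("<dnm> linear time-varying dynamic network model\n")
  cat(sprintf("  subject: %s | %d channels | %d windows of %d samples (%g ms @ %g Hz)\n",
              x$subject_id, length(x$channel_labels), x$n_windows,
              x$window_len_samples, x$window_duration_ms, x$fs))
  nbad <- sum(!x$valid)
  if (nbad > 0) cat("  ", nbad, " window(s) skipped\n", sep = "")
  invisible(x)
}

#' @export
summary.dnm <- function(object, ...) {
  sr <- vapply(object$A_seq[object$valid],
               function(A) max(Mod(eigen(A, only.values = TRUE)$values)),
               numeric(1))
  out <- list(n_windows = object$n_windows,
              n_valid = sum(object$valid),
              n_flagged = sum(!is.na(object$cond_flags)),
              channels = object$channel_labels,
              spectral_radius = summary(sr))
  class(out) <- "summary.dnm"
  out
}

#' @export
print.summary.dnm <- function(x, ...) {
  cat("Dynamic network model:", x$n_valid, "of", x$n_windows,
      "windows fitted (", x$n_flagged, "flagged )\n")
  cat("Per-window spectral radius:\n")
  print(x$spectral_radius)
  invisible(x)
}

#' Extract the state-transition matrices
#'
#' @param object a [fit_dnm()] fit.
#' @param ... unused.
#' @return N x N x M array of transition matrices (skipped windows are NA
#'   slices).
#' @export
coef.dnm <- function(object, ...) {
  N <- length(object$channel_labels)
  out <- array(NA_real_, c(N, N, object$n_windows),
               dimnames = list(object$channel_labels,
                               object$channel_labels, NULL))
  for (k in which(object$valid)) out[, , k] <- object$A_seq[[k]]
  out
}

#' One-step-ahead predictions from a fitted DNM
#'
#' Applies each window's transition matrix to the window's own samples,
#' giving the model's one-step prediction of x(t+1) from x(t).
#'
#' @param object a `dnm` fit.
#' @param newdata an [eeg_recording] segmented with the fit's window
#'   length; defaults to refusing silently absent data (the fit stores no
#'   raw samples), so `newdata` is required.
#' @param ... unused.
#' @return Channels x samples matrix of predictions, aligned with samples
#'   `2..L` of every window (other columns NA).
#' @export
predict.dnm <- function(object, newdata, ...) {
  if (missing(newdata))
    stop("predict.dnm needs `newdata`: the fit does not retain samples",
         call. = FALSE)
  stopifnot_recording(newdata)
  if (!identical(newdata$channel_labels, object$channel_labels))
    stop("newdata channels do not match the fitted model", call. = FALSE)
  L <- object$window_len_samples
  pred <- matrix(NA_real_, nrow(newdata$data), ncol(newdata$data),
                 dimnames = dimnames(newdata$data))
  M <- min(object$n_windows, floor(ncol(newdata$data) / L))
  for (k in seq_len(M)) {
    if (!object$valid[k]) next
    idx <- ((k - 1L) * L + 1L):(k * L)
    X <- newdata$data[, idx[-L], drop = FALSE]
    pred[, idx[-1L]] <- object$A_seq[[k]] %*% X
  }
  pred
}

#' Innovation residuals of a fitted DNM
#'
#' @inheritParams predict.dnm
#' @return Channels x samples matrix of one-step prediction errors
#'   (NA where no prediction is defined).
#' @export
residuals.dnm <- function(object, newdata, ...) {
  pred <- predict(object, newdata)
  newdata$data - pred
}

#' Simulate from a fitted DNM
#'
#' Iterates x(t+1) = A_k x(t) + e(t) through the fitted window sequence
#' with i.i.d. Gaussian innovations, producing a surrogate recording with
#' the model's time-varying linear dynamics.
#'
#' @param object a `dnm` fit.
#' @param nsim number of surrogate recordings.
#' @param seed integer seed.
#' @param noise_sd innovation standard deviation in microvolts.
#' @param ... unused.
#' @return An [eeg_recording] (or list of them when `nsim > 1`).
#' @export
simulate.dnm <- function(object, nsim = 1, seed = NULL, noise_sd = 1, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(object$channel_labels)
  L <- object$window_len_samples
  one <- function() {
    x <- numeric(N)
    out <- matrix(0, N, object$n_windows * L)
    col <- 1L
    for (k in seq_len(object$n_windows)) {
      A <- if (object$valid[k]) object$A_seq[[k]] else diag(0, N)
      for (j in seq_len(L)) {
        x <- as.numeric(A %*% x) + rnorm(N, sd = noise_sd)
        out[, col] <- x
        col <- col + 1L
      }
    }
    eeg_recording(out, fs = object$fs,
                  channel_labels = object$channel_labels,
                  subject_id = paste0(object$subject_id, "-sim"))
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' Plot a fitted DNM
#'
#' Displays the sink-index heatmap of the fit (channels x windows), the
#' standard visual summary of the model's time-varying source-sink
#' structure.
#'
#' @param x a `dnm` fit.
#' @param ... passed to [plot.sink_map()].
#' @export
plot.dnm <- function(x, ...) {
  plot(sink_map(x), ...)
}
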