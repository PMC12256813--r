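#' Hjorth parameters of a signal
#'
#' Time-domain descriptors: activity (variance), mobility (root variance
#' ratio of the first difference to the signal) and complexity (mobility
#' of the first difference relative to the signal's own mobility). For a
#' pure tone of angular frequency w rad/sample, mobility approaches w and
#' complexity approaches 1 as sampling density grows.
#'
#' @param x numeric vector, length >= 3, nonzero variance.
#' @return Named numeric vector `c(activity, mobility, complexity)`.
#' @export
hjorth <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L)
    stop("degenerate input: need at least 3 samples", call. = FALSE)
  v0 <- stats::var(x)
  if (!is.finite(v0) || v0 == 0)
    stop("degenerate input: zero-variance signal", call. = FALSE)
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- stats::var(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  cmp <- if (v1 > 0) sqrt(v2 / v1) / mob else NA_real_
  c(activity = v0, mobility = mob, complexity = cmp)
}

.band_edges <- list(delta = c(1, 4), theta = c(4, 8),
                    alpha = c(8, 12), beta = c(12, 30))

# segment start indices for win_s windows with fractional overlap
.segment_starts <- function(n, fs, win_s, overlap) {
  L <- round(win_s * fs)
  if (n < L)
    stop("degenerate input: recording shorter than one ", win_s,
         " s segment", call. = FALSE)
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = hop)
  list(starts = starts, len = L)
}

#' Band-power features with regional ratios
#'
#' Mean spectral power in the delta (1-4 Hz), theta (4-8), alpha (8-12)
#' and beta (12-30 Hz) bands, from squared FFT magnitudes of Hann-windowed
#' segments averaged across the recording; then averaged over the FT and
#' CPO electrode groups, with the per-band FT/CPO ratio. The alpha-band
#' ratio is the spectral classification feature.
#'
#' @param rec a preprocessed [eeg_recording] with fs > 60 Hz.
#' @param scheme a [region_scheme()].
#' @param win_s segment length in seconds (default 8).
#' @param overlap fractional segment overlap (default 0.5).
#' @return Object of class `band_power_features`: list with
#'   `per_channel` (bands x channels power matrix), `ft`, `cpo` (per-band
#'   group means) and `ratio` (per-band FT/CPO).
#' @export
band_power <- function(rec, scheme = region_scheme(), win_s = 8,
                       overlap = 0.5) {
  stopifnot_recording(rec)
  if (rec$fs / 2 <= 30)
    stop("sampling rate too low for the 12-30 Hz band", call. = FALSE)
  seg <- .segment_starts(n_samples(rec), rec$fs, win_s, overlap)
  L <- seg$len
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))   # Hann
  freqs <- (seq_len(L) - 1L) * rec$fs / L
  masks <- lapply(.band_edges, function(e) freqs > e[1] & freqs <= e[2])
  pw <- matrix(0, length(masks), n_channels(rec),
               dimnames = list(names(masks), rec$channel_labels))
  for (s in seg$starts) {
    seg_data <- rec$data[, s:(s + L - 1L), drop = FALSE]
    for (ch in seq_len(nrow(seg_data))) {
      spec <- Mod(stats::fft(seg_data[ch, ] * w))^2
      for (b in seq_along(masks)) pw[b, ch] <- pw[b, ch] + sum(spec[masks[[b]]])
    }
  }
  pw <- pw / length(seg$starts)
  ft_ch <- intersect(scheme$ft, rec$channel_labels)
  cpo_ch <- intersect(scheme$cpo, rec$channel_labels)
  ft <- rowMeans(pw[, ft_ch, drop = FALSE])
  cpo <- rowMeans(pw[, cpo_ch, drop = FALSE])
  structure(list(per_channel = pw, ft = ft, cpo = cpo,
                 ratio = ifelse(cpo > 0, ft / cpo, NA_real_)),
            class = "band_power_features")
}

#' @export
print.band_power_features <- function(x, ...) {
  cat("Band power (FT | CPO | ratio):\n")
  print(round(cbind(FT = x$ft, CPO = x$cpo, ratio = x$ratio), 4))
  invisible(x)
}

# Orthogonal wavelet decomposition low-pass filters (analysis side).
.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
          -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523),
  sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427),
  coif2 = c(-0.0007205494453645122, -0.0018232088707029932,
            0.0056114348193944995, 0.023680171946334084, -0.0594344186464569,
            -0.0764885990783064, 0.41700518442169254, 0.8127236354455423,
            0.3861100668211622, -0.06737255472196302, -0.04146493678175915,
            0.016387336463522112)
)

# one analysis level with periodic extension: circular convolution with the
# low/high-pass pair, then dyadic downsampling
.dwt_level <- function(x, h) {
  n <- length(x)
  if (n %% 2L == 1L) { x <- c(x, x[n]); n <- n + 1L }
  g <- rev(h) * (-1)^(seq_along(h) - 1L)     # quadrature mirror
  hp <- c(h, numeric(n - length(h)))
  gp <- c(g, numeric(n - length(g)))
  fx <- stats::fft(x)
  a <- Re(stats::fft(fx * stats::fft(hp), inverse = TRUE)) / n
  d <- Re(stats::fft(fx * stats::fft(gp), inverse = TRUE)) / n
  idx <- seq(2L, n, by = 2L)
  list(approx = a[idx], detail = d[idx])
}

#' Dyadic wavelet decomposition
#'
#' Multi-level dyadic analysis with one of the supported orthogonal
#' wavelet families, using periodic signal extension. Returns the detail
#' coefficient sequences per level (level 1 = finest).
#'
#' @param x numeric signal.
#' @param template wavelet family: `"db4"` (default), `"sym4"`, `"coif2"`
#'   or `"haar"`.
#' @param levels number of decomposition levels (default 5).
#' @return List with `details` (list of numeric vectors, one per level)
#'   and `approx` (the final approximation).
#' @export
dwt_dyadic <- function(x, template = "db4", levels = 5) {
  if (!template %in% names(.wavelet_filters))
    stop("config error: unknown wavelet template '", template, "'",
         call. = FALSE)
  h <- .wavelet_filters[[template]]
  details <- vector("list", levels)
  a <- as.numeric(x)
  for (lev in seq_len(levels)) {
    if (length(a) < 2L)
      stop("signal too short for ", levels, " decomposition levels",
           call. = FALSE)
    step <- .dwt_level(a, h)
    details[[lev]] <- step$detail
    a <- step$approx
  }
  list(details = details, approx = a)
}

#' Time-frequency feature vector
#'
#' The wavelet/Hjorth baseline feature set: the recording is cut into
#' `win_s`-second windows with fractional `overlap`; per window and
#' channel a `levels`-deep dyadic wavelet decomposition is computed and
#' the Hjorth triplet (activity, mobility, complexity) taken on each
#' detail subband. Features are averaged across windows, giving
#' channels x levels x 3 values — 285 for the 19-channel montage.
#'
#' @inheritParams band_power
#' @param template wavelet family (see [dwt_dyadic()]).
#' @param levels decomposition depth (default 5).
#' @return Named numeric vector of length `channels * levels * 3`, names
#'   `<channel>.d<level>.<parameter>`.
#' @export
timefreq_features <- function(rec, template = "db4", win_s = 8,
                              overlap = 0.5, levels = 5) {
  stopifnot_recording(rec)
  seg <- .segment_starts(n_samples(rec), rec$fs, win_s, overlap)
  L <- seg$len
  chans <- rec$channel_labels
  acc <- NULL
  for (s in seg$starts) {
    feats <- numeric(0)
    for (ch in chans) {
      dec <- dwt_dyadic(rec$data[ch, s:(s + L - 1L)], template, levels)
      for (lev in seq_len(levels)) {
        hj <- hjorth(dec$details[[lev]])
        names(hj) <- paste0(ch, ".d", lev, ".", names(hj))
        feats <- c(feats, hj)
      }
    }
    acc <- if (is.null(acc)) feats else acc + feats
  }
  acc / length(seg$starts)
}

#' PCA reduction fitted on training rows only
#'
#' Principal components are estimated from the training matrix alone
#' (centering included) and both matrices are projected onto the leading
#' `k` orthonormal components, so no test-set information leaks into the
#' reduction.
#'
#' @param train_features,test_features numeric matrices with identical
#'   columns (subjects x features); `test_features` may be NULL.
#' @param k number of components (default 5).
#' @return List with `train`, `test` (projected matrices), `rotation`,
#'   `center`, `sdev`.
#' @export
pca_reduce <- function(train_features, test_features = NULL, k = 5) {
  train_features <- as.matrix(train_features)
  if (k > ncol(train_features))
    stop("config error: k exceeds feature dimension", call. = FALSE)
  if (nrow(train_features) < k)
    stop("config error: fewer training rows than components", call. = FALSE)
  pc <- stats::prcomp(train_features, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  proj <- function(m)
    sweep(as.matrix(m), 2, pc$center) %*% rot
  list(train = proj(train_features),
       test = if (!is.null(test_features)) proj(test_features),
       rotation = rot, center = pc$center, sdev = pc$sdev[seq_len(k)])
}
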