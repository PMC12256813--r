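#' Preprocessing configuration
#'
#' The resting-state preprocessing chain: downsample to `target_fs`,
#' zero-phase Butterworth band-pass `bp_lo`-`bp_hi` Hz, then zero-phase
#' Butterworth band-stop notches at the mains frequency and every
#' harmonic below Nyquist, each `notch_stop_bw` Hz wide. An optional
#' `artefact_hook` (a function `eeg_recording -> eeg_recording`) runs
#' last, so external artefact-removal tools (ASR, ICA pipelines) can be
#' plugged in; the default is the identity.
#'
#' @param target_fs output sampling rate, Hz (default 250).
#' @param bp_lo,bp_hi band-pass corner frequencies, Hz (defaults 0.5, 48).
#' @param notch_base mains frequency, Hz (default 50).
#' @param notch_stop_bw notch stopband width, Hz (default 2).
#' @param filter_order Butterworth order (default 4), applied
#'   forward-backward.
#' @param artefact_hook optional cleaning function applied after
#'   filtering.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 250, bp_lo = 0.5, bp_hi = 48,
                              notch_base = 50, notch_stop_bw = 2,
                              filter_order = 4, artefact_hook = NULL) {
  if (!(bp_lo > 0 && bp_lo < bp_hi && bp_hi < target_fs / 2))
    stop("config error: need 0 < bp_lo < bp_hi < target_fs/2",
         call. = FALSE)
  if (notch_base >= target_fs / 2)
    stop("config error: notch_base must lie below Nyquist", call. = FALSE)
  if (!is.null(artefact_hook) && !is.function(artefact_hook))
    stop("config error: artefact_hook must be a function", call. = FALSE)
  structure(list(target_fs = target_fs, bp_lo = bp_lo, bp_hi = bp_hi,
                 notch_base = notch_base, notch_stop_bw = notch_stop_bw,
                 filter_order = filter_order, artefact_hook = artefact_hook),
            class = "preprocess_config")
}

# zero-phase filtering of every channel with one filter object
.filtfilt_rows <- function(data, filt) {
  t(apply(data, 1, function(x) signal::filtfilt(filt, x)))
}

#' Preprocess a recording
#'
#' Applies the chain of [preprocess_config()]: anti-aliased resampling to
#' the target rate, zero-phase Butterworth band-pass (realized as a
#' high-pass/low-pass cascade, which is numerically robust at the 0.5 Hz
#' corner), zero-phase band-stop notches at the mains frequency and its
#' harmonics below Nyquist, then the artefact hook. Channel order is
#' preserved throughout.
#'
#' @param rec an [eeg_recording] with `fs >= target_fs`.
#' @param cfg a [preprocess_config()].
#' @return A preprocessed [eeg_recording] at `target_fs`.
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  stopifnot_recording(rec)
  if (rec$fs < cfg$target_fs)
    stop("upsampling error: recording rate ", rec$fs,
         " Hz below target ", cfg$target_fs, " Hz", call. = FALSE)
  ord <- cfg$filter_order
  min_len <- 10L * 3L * ord   # ~10 filter lengths
  if (n_samples(rec) < min_len)
    stop("degenerate input: recording shorter than ", min_len,
         " samples", call. = FALSE)
  # remove per-channel DC before any filtering: a large offset would ring
  # at the edges of the zero-phase filters
  data <- rec$data - rowMeans(rec$data)
  fs <- rec$fs
  # 1. downsample (polyphase resampler with its own anti-alias low-pass)
  if (fs != cfg$target_fs) {
    rat <- .rational_ratio(cfg$target_fs / fs)
    n_out <- round(n_samples(rec) * cfg$target_fs / fs)
    res <- t(apply(data, 1, function(x)
      signal::resample(x, p = rat[1], q = rat[2])))
    # resample can come back one sample long/short of the exact round()
    if (ncol(res) > n_out) res <- res[, seq_len(n_out), drop = FALSE]
    if (ncol(res) < n_out)
      res <- cbind(res, res[, rep(ncol(res), n_out - ncol(res)),
                            drop = FALSE])
    data <- res
    fs <- cfg$target_fs
  }
  nyq <- fs / 2
  # 2. band-pass as zero-phase high-pass + low-pass cascade
  hp <- signal::butter(ord, cfg$bp_lo / nyq, type = "high")
  lp <- signal::butter(ord, cfg$bp_hi / nyq, type = "low")
  data <- .filtfilt_rows(.filtfilt_rows(data, hp), lp)
  # 3. notch at the mains frequency and all harmonics below Nyquist
  harmonics <- seq(cfg$notch_base, nyq - cfg$notch_stop_bw / 2,
                   by = cfg$notch_base)
  for (f0 in harmonics) {
    edges <- c(f0 - cfg$notch_stop_bw / 2, f0 + cfg$notch_stop_bw / 2) / nyq
    bs <- signal::butter(2, edges, type = "stop")
    data <- .filtfilt_rows(data, bs)
  }
  out <- eeg_recording(data, fs = fs, channel_labels = rec$channel_labels,
                       subject_id = rec$subject_id)
  if (!is.null(cfg$artefact_hook)) {
    out <- cfg$artefact_hook(out)
    stopifnot_recording(out)
  }
  out
}

# small-denominator rational approximation of a resampling ratio
.rational_ratio <- function(x, max_den = 1000) {
  best <- c(round(x), 1)
  best_err <- abs(x - best[1])
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    err <- abs(x - p / q)
    if (err < best_err - 1e-12) {
      best <- c(p, q)
      best_err <- err
    }
    if (best_err < 1e-9) break
  }
  best
}
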