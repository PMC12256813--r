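#' Construct a multichannel EEG recording
#'
#' Container for a channel-by-sample matrix of scalp EEG in microvolts,
#' together with its sampling rate and subject metadata. All ingestion,
#' preprocessing and modelling functions in the package operate on this
#' class.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector, one unique label per row of
#'   `data`; mapped onto canonical 10-20 names when possible.
#' @param subject_id subject identifier string.
#' @return Object of class `eeg_recording`: list with elements `data`,
#'   `fs`, `channel_labels`, `subject_id`, `duration_s`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(19 * 500), 19), fs = 250)
#' rec
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          subject_id = "anonymous") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L)
    stop("degenerate input: a recording needs at least 2 channels",
         call. = FALSE)
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(data) == 19L) canonical_channels()
                      else paste0("ch", seq_len(nrow(data)))
  }
  channel_labels <- canonicalize_channels(as.character(channel_labels))
  if (length(channel_labels) != nrow(data))
    stop("metadata error: ", length(channel_labels), " labels for ",
         nrow(data), " data rows", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("metadata error: duplicate channel labels", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("sampling rate must be a positive scalar", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("recording contains NaN/Inf values", call. = FALSE)
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = as.numeric(fs), channel_labels = channel_labels,
         subject_id = as.character(subject_id),
         duration_s = ncol(data) / fs),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> subject:", x$subject_id, "\n")
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$duration_s))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

stopifnot_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording"))
    stop("expected an 'eeg_recording' object", call. = FALSE)
  invisible(rec)
}
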