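#' Read an EEG recording from a standard format
#'
#' Dispatches on format: EDF/EDF+ (`"edf"`), EEGLAB (`"eeglab_set"`, with
#' optional companion `.fdt`) or plain CSV (`"array_csv"`: header row of
#' channel labels, one row per sample). With `format = "auto"` the file
#' extension decides. Channel labels are mapped onto canonical 10-20
#' names case-insensitively.
#'
#' @param path input file.
#' @param format one of `"auto"`, `"edf"`, `"eeglab_set"`, `"array_csv"`.
#' @param fs sampling rate in Hz, used (and required) only for CSV input,
#'   which carries no rate metadata.
#' @param subject_id optional subject identifier.
#' @return An [eeg_recording].
#' @export
read_recording <- function(path, format = c("auto", "edf", "eeglab_set",
                                            "array_csv"),
                           fs = NULL, subject_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", set = "eeglab_set", csv = "array_csv",
                     stop("format error: cannot infer format of ", path,
                          call. = FALSE))
  }
  switch(format,
         edf = read_edf(path, subject_id = subject_id),
         eeglab_set = read_set(path, subject_id = subject_id),
         array_csv = read_csv_recording(path, fs = fs,
                                        subject_id = subject_id))
}

#' Read a recording from a CSV matrix
#'
#' Expects a header row of channel labels and one row per sample
#' (columns are channels). CSV carries no sampling-rate metadata, so `fs`
#' must be supplied.
#'
#' @param path CSV file.
#' @param fs sampling rate in Hz.
#' @param subject_id optional subject identifier.
#' @return An [eeg_recording].
#' @export
read_csv_recording <- function(path, fs, subject_id = NULL) {
  if (!file.exists(path)) stop("format error: no such file: ", path,
                               call. = FALSE)
  if (is.null(fs))
    stop("metadata error: CSV input needs an explicit sampling rate `fs`",
         call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("degenerate input: fewer than 2 channels", call. = FALSE)
  eeg_recording(t(as.matrix(df)), fs = fs, channel_labels = names(df),
                subject_id = if (is.null(subject_id)) basename(path)
                             else subject_id)
}

#' Write a recording as a CSV matrix
#'
#' Inverse of [read_csv_recording()]: header row of channel labels, one
#' row per sample.
#'
#' @param rec an [eeg_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_recording <- function(rec, path) {
  stopifnot_recording(rec)
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# group label harmonization: the cohort convention uses FTD / AD / HC;
# BIDS-style single letters (F/A/C) are accepted
.normalize_group <- function(g) {
  g <- toupper(trimws(as.character(g)))
  map <- c(F = "FTD", FTD = "FTD", A = "AD", AD = "AD", ALZ = "AD",
           ALZHEIMER = "AD", C = "HC", HC = "HC", CN = "HC",
           CONTROL = "HC", HEALTHY = "HC")
  out <- unname(map[g])
  if (anyNA(out))
    stop("validation error: unknown group label(s): ",
         paste(unique(g[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Read a cohort table from a BIDS-like directory
#'
#' Reads `participants.tsv` (tab-separated, with participant_id, Gender,
#' Age, Group and MMSE columns in any capitalization) and resolves each
#' subject's recording file under `<dir>/<participant_id>/eeg/` when
#' present. Group labels are normalized to FTD / AD / HC.
#'
#' @param dir cohort directory containing `participants.tsv`.
#' @return data.frame with columns `subject_id`, `group`, `sex`, `age`,
#'   `mmse`, `recording_path` (NA when no file was found).
#' @export
read_cohort <- function(dir) {
  tsv <- file.path(dir, "participants.tsv")
  if (!file.exists(tsv))
    stop("metadata error: no participants.tsv under ", dir, call. = FALSE)
  df <- utils::read.delim(tsv, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cols <- tolower(names(df))
  pick <- function(nm) {
    i <- match(nm, cols)
    if (is.na(i)) stop("metadata error: participants.tsv lacks a '", nm,
                       "' column", call. = FALSE)
    df[[i]]
  }
  subject_id <- as.character(pick("participant_id"))
  if (anyDuplicated(subject_id))
    stop("validation error: duplicate participant_id", call. = FALSE)
  mmse <- suppressWarnings(as.numeric(pick("mmse")))
  if (any(!is.na(mmse) & (mmse < 0 | mmse > 30)))
    stop("validation error: MMSE outside [0, 30]", call. = FALSE)
  out <- data.frame(
    subject_id = subject_id,
    group = .normalize_group(pick("group")),
    sex = as.character(pick("gender")),
    age = suppressWarnings(as.numeric(pick("age"))),
    mmse = mmse,
    stringsAsFactors = FALSE)
  out$recording_path <- vapply(out$subject_id, function(sid) {
    eegdir <- file.path(dir, sid, "eeg")
    hits <- c(list.files(eegdir, pattern = "\\.set$", full.names = TRUE),
              list.files(eegdir, pattern = "\\.edf$", full.names = TRUE),
              Filter(file.exists,
                     file.path(dir, paste0(sid, c(".set", ".edf", ".csv")))))
    if (length(hits) > 0) hits[1] else NA_character_
  }, "")
  counts <- table(out$group)
  message("cohort: ", nrow(out), " subjects (",
          paste(names(counts), counts, sep = " = ", collapse = ", "), ")")
  out
}
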