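# Minimal EDF/EDF+ support: fixed-layout ASCII header (256 bytes + 256 per
# signal) followed by data records of 16-bit little-endian integers scaled
# between the declared physical and digital ranges. Continuous recordings
# only; annotation channels are ignored on read.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.edf_num <- function(x, width) .edf_pad(format(x, trim = TRUE, digits = 8), width)

#' Write a recording to an EDF file
#'
#' Each channel is scaled to the signed 16-bit range of its own physical
#' min/max (microvolts), so values round-trip within one quantization
#' step. Data records are one second long; a trailing partial second is
#' dropped, matching the continuous-record EDF layout.
#'
#' @param rec an [eeg_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot_recording(rec)
  if (rec$fs != round(rec$fs))
    stop("EDF export needs an integer sampling rate", call. = FALSE)
  ns <- n_channels(rec)
  spr <- as.integer(rec$fs)              # samples per 1 s record
  n_rec <- floor(n_samples(rec) / spr)
  if (n_rec < 1L) stop("recording shorter than one 1 s EDF record",
                       call. = FALSE)
  pmin_ <- apply(rec$data, 1, min); pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(rec$subject_id, 80),
    .edf_pad("recording", 80),
    .edf_pad("01.01.26", 8), .edf_pad("00.00.00", 8),
    .edf_num(256L * (1L + ns), 8),
    .edf_pad("", 44),
    .edf_num(n_rec, 8),
    .edf_num(1L, 8),
    .edf_num(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)                           # transducer
  field(rep("uV", ns), 8)                          # physical dimension
  field(format(pmin_, trim = TRUE, digits = 8), 8)
  field(format(pmax_, trim = TRUE, digits = 8), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                           # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)                           # reserved
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((rec$data[ch, idx] - pmin_[ch]) / scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into a recording
#'
#' Parses the fixed-layout header, honours the per-signal physical
#' dimension and calibration, and returns the signal matrix in microvolts
#' (millivolt channels are rescaled). EDF+ annotation channels are
#' dropped. All retained channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @param subject_id optional subject identifier; defaults to the header's
#'   patient field.
#' @return An [eeg_recording].
#' @export
read_edf <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("format error: no such file: ", path,
                               call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0"))
    stop("format error: not an EDF file (bad version field)", call. = FALSE)
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("format error: bad signal count",
                                 call. = FALSE)
  many <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- many(16)
  many(80)
  dims <- many(8)
  pmin_ <- as.numeric(many(8)); pmax_ <- as.numeric(many(8))
  dmin <- as.numeric(many(8)); dmax <- as.numeric(many(8))
  many(80)
  spr <- as.integer(many(8))
  many(32)
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (sum(keep) < 2L)
    stop("degenerate input: fewer than 2 signal channels", call. = FALSE)
  if (length(unique(spr[keep])) != 1L)
    stop("metadata error: channels with mixed sampling rates", call. = FALSE)
  fs <- spr[keep][1] / rec_dur
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  per_rec <- sum(spr)
  data <- matrix(0, sum(keep), n_rec * spr[keep][1])
  raw_all <- readBin(con, integer(), n = n_rec * per_rec, size = 2,
                     signed = TRUE, endian = "little")
  if (length(raw_all) < n_rec * per_rec)
    stop("format error: truncated EDF data section", call. = FALSE)
  offs <- c(0L, cumsum(spr))
  row <- 0L
  for (ch in seq_len(ns)) {
    if (!keep[ch]) next
    row <- row + 1L
    cols <- 0L
    for (r in seq_len(n_rec)) {
      base <- (r - 1L) * per_rec + offs[ch]
      vals <- raw_all[(base + 1L):(base + spr[ch])]
      data[row, (cols + 1L):(cols + spr[ch])] <-
        (vals - dmin[ch]) * scale[ch] + pmin_[ch]
      cols <- cols + spr[ch]
    }
  }
  unit_scale <- ifelse(grepl("^mV$", dims[keep], ignore.case = TRUE),
                       1000, 1)
  data <- data * unit_scale
  lbl <- labels[keep]
  if (anyDuplicated(canonicalize_channels(lbl)))
    stop("metadata error: duplicate channel labels", call. = FALSE)
  eeg_recording(data, fs = fs, channel_labels = lbl,
                subject_id = if (is.null(subject_id)) {
                  if (nzchar(patient)) patient else basename(path)
                } else subject_id)
}
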