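# Minimal MAT-file v5 support, sufficient for EEGLAB .set headers: numeric,
# char, cell and struct arrays, with zlib-compressed elements handled.
# Little-endian files only (the format MATLAB and EEGLAB write on all
# mainstream platforms).

.ceil8 <- function(n) (n + 7L) %/% 8L * 8L

.mat_u32 <- function(buf, pos) {
  v <- readBin(buf[pos:(pos + 3L)], "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else as.numeric(v)
}

# read one tag at pos; handles the packed "small data element" form
.mat_tag <- function(buf, pos) {
  word1 <- .mat_u32(buf, pos)
  small_bytes <- word1 %/% 65536
  if (small_bytes > 0) {
    list(type = word1 %% 65536, nbytes = small_bytes, data = pos + 4L,
         next_pos = pos + 8L)
  } else {
    nb <- .mat_u32(buf, pos + 4L)
    list(type = word1, nbytes = nb, data = pos + 8L,
         next_pos = pos + 8L + .ceil8(nb))
  }
}

# numeric payload of a subelement, by mi data type
.mat_numeric <- function(buf, tag) {
  rng <- if (tag$nbytes > 0) buf[tag$data:(tag$data + tag$nbytes - 1L)]
         else raw(0)
  switch(as.character(tag$type),
    "1" = as.numeric(readBin(rng, "integer", n = tag$nbytes, size = 1,
                             signed = TRUE)),
    "2" = as.numeric(readBin(rng, "integer", n = tag$nbytes, size = 1,
                             signed = FALSE)),
    "3" = as.numeric(readBin(rng, "integer", n = tag$nbytes / 2, size = 2,
                             signed = TRUE, endian = "little")),
    "4" = as.numeric(readBin(rng, "integer", n = tag$nbytes / 2, size = 2,
                             signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(rng, "integer", n = tag$nbytes / 4, size = 4,
                             endian = "little")),
    "6" = {
      v <- readBin(rng, "integer", n = tag$nbytes / 4, size = 4,
                   endian = "little")
      ifelse(v < 0, v + 2^32, v)
    },
    "7" = readBin(rng, "numeric", n = tag$nbytes / 4, size = 4,
                  endian = "little"),
    "9" = readBin(rng, "numeric", n = tag$nbytes / 8, size = 8,
                  endian = "little"),
    stop("format error: unsupported MAT data type ", tag$type,
         call. = FALSE)
  )
}

.mat_chars <- function(buf, tag) {
  if (tag$nbytes == 0) return("")
  rng <- buf[tag$data:(tag$data + tag$nbytes - 1L)]
  codes <- switch(as.character(tag$type),
    "16" = , "1" = , "2" = as.integer(rng),
    "4" = , "17" = , "3" = readBin(rng, "integer", n = tag$nbytes / 2,
                                   size = 2, signed = FALSE,
                                   endian = "little"),
    stop("format error: unsupported MAT char type ", tag$type,
         call. = FALSE))
  intToUtf8(codes[codes > 0])
}

# parse one full data element (returns value, name, next_pos)
.mat_element <- function(buf, pos) {
  tag <- .mat_tag(buf, pos)
  if (tag$type == 15) {                       # miCOMPRESSED
    z <- memDecompress(buf[tag$data:(tag$data + tag$nbytes - 1L)],
                       type = "gzip")
    inner <- .mat_element(z, 1L)
    inner$next_pos <- tag$next_pos
    return(inner)
  }
  if (tag$type != 14)
    stop("format error: expected a matrix element, found type ", tag$type,
         call. = FALSE)
  p <- tag$data
  flags_tag <- .mat_tag(buf, p)
  class_id <- as.integer(buf[flags_tag$data])
  p <- flags_tag$next_pos
  dims_tag <- .mat_tag(buf, p)
  dims <- readBin(buf[dims_tag$data:(dims_tag$data + dims_tag$nbytes - 1L)],
                  "integer", n = dims_tag$nbytes / 4, size = 4,
                  endian = "little")
  p <- dims_tag$next_pos
  name_tag <- .mat_tag(buf, p)
  name <- if (name_tag$nbytes > 0)
    rawToChar(buf[name_tag$data:(name_tag$data + name_tag$nbytes - 1L)])
  else ""
  p <- name_tag$next_pos
  value <- switch(as.character(class_id),
    "6" = , "7" = , "8" = , "9" = , "10" = , "11" = , "12" = , "13" = {
      data_tag <- .mat_tag(buf, p)
      v <- .mat_numeric(buf, data_tag)
      if (length(dims) == 2L && any(dims == 1L)) v
      else array(v, dim = dims)
    },
    "4" = {                                    # char
      data_tag <- .mat_tag(buf, p)
      .mat_chars(buf, data_tag)
    },
    "1" = {                                    # cell
      n <- prod(dims)
      out <- vector("list", n)
      for (i in seq_len(n)) {
        el <- .mat_element(buf, p)
        out[[i]] <- el$value
        p <- el$next_pos
      }
      out
    },
    "2" = {                                    # struct
      fl_tag <- .mat_tag(buf, p)
      flen <- readBin(buf[fl_tag$data:(fl_tag$data + 3L)], "integer",
                      size = 4, endian = "little")
      p <- fl_tag$next_pos
      fn_tag <- .mat_tag(buf, p)
      nf <- fn_tag$nbytes / flen
      fields <- vapply(seq_len(nf), function(i) {
        s <- fn_tag$data + (i - 1L) * flen
        chunk <- buf[s:(s + flen - 1L)]
        rawToChar(chunk[chunk != as.raw(0)])
      }, "")
      p <- fn_tag$next_pos
      n <- prod(dims)
      elems <- vector("list", n)
      for (i in seq_len(n)) {
        one <- stats::setNames(vector("list", nf), fields)
        for (f in seq_len(nf)) {
          el <- .mat_element(buf, p)
          one[[f]] <- el$value
          p <- el$next_pos
        }
        elems[[i]] <- one
      }
      if (n == 1L) elems[[1L]] else elems
    },
    stop("format error: unsupported MAT array class ", class_id,
         call. = FALSE)
  )
  list(value = value, name = name, next_pos = tag$next_pos)
}

# all top-level variables of a v5 MAT file, as a named list
.mat_read_file <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 136)
    stop("format error: not a MAT v5 file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 128)
  endmark <- rawToChar(hdr[127:128])
  if (endmark == "MI")
    stop("format error: big-endian MAT files are not supported",
         call. = FALSE)
  if (endmark != "IM")
    stop("format error: not a MAT v5 file: ", path, call. = FALSE)
  buf <- readBin(con, "raw", sz - 128)
  vars <- list()
  pos <- 1L
  while (pos + 7L <= length(buf)) {
    el <- .mat_element(buf, pos)
    if (nzchar(el$name)) vars[[el$name]] <- el$value
    pos <- el$next_pos
  }
  vars
}

#' Read an EEGLAB .set file into a recording
#'
#' Parses the MAT v5 container for the `EEG` structure (channel count,
#' sampling rate, channel locations) and loads the signal matrix either
#' from the in-file `data` field or from the companion `.fdt` float32
#' file it names. Continuous (single-trial) datasets only.
#'
#' @param path `.set` file path.
#' @param subject_id optional subject identifier (defaults to the setname
#'   or file name).
#' @return An [eeg_recording].
#' @export
read_set <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("format error: no such file: ", path,
                               call. = FALSE)
  vars <- .mat_read_file(path)
  EEG <- vars$EEG
  if (is.null(EEG)) {
    # some writers store the fields as individual top-level variables
    if (all(c("nbchan", "srate", "data") %in% names(vars))) EEG <- vars
    else stop("metadata error: no EEG structure in ", path, call. = FALSE)
  }
  need <- c("nbchan", "srate", "data")
  if (!all(need %in% names(EEG)))
    stop("metadata error: EEG structure lacks ",
         paste(setdiff(need, names(EEG)), collapse = ", "), call. = FALSE)
  nbchan <- as.integer(EEG$nbchan[1])
  srate <- as.numeric(EEG$srate[1])
  trials <- if (!is.null(EEG$trials)) as.integer(EEG$trials[1]) else 1L
  if (!is.na(trials) && trials > 1L)
    stop("format error: epoched datasets are not supported", call. = FALSE)
  data <- EEG$data
  if (is.character(data)) {
    fdt <- file.path(dirname(path), basename(data))
    if (!file.exists(fdt)) fdt <- sub("\\.set$", ".fdt", path)
    if (!file.exists(fdt))
      stop("format error: companion data file not found: ", data,
           call. = FALSE)
    n_float <- file.size(fdt) / 4
    fcon <- file(fdt, "rb")
    on.exit(close(fcon))
    vals <- readBin(fcon, "numeric", n = n_float, size = 4,
                    endian = "little")
    data <- matrix(vals, nrow = nbchan)
  }
  data <- as.matrix(data)
  if (nrow(data) != nbchan && ncol(data) == nbchan) data <- t(data)
  labels <- if (!is.null(EEG$chanlocs)) {
    cl <- EEG$chanlocs
    if (!is.null(names(cl))) cl <- list(cl)   # scalar struct
    vapply(cl, function(x) as.character(x$labels), "")
  } else paste0("ch", seq_len(nbchan))
  if (is.null(subject_id)) {
    subject_id <- if (!is.null(EEG$setname) && nzchar(EEG$setname))
      as.character(EEG$setname) else basename(path)
  }
  eeg_recording(data, fs = srate, channel_labels = labels,
                subject_id = subject_id)
}

## ---- minimal uncompressed MAT v5 writer (for .set export/fixtures) ----

.w_el <- function(type, payload) {
  nb <- length(payload)
  tag <- writeBin(as.integer(c(type, nb)), raw(), size = 4,
                  endian = "little")
  pad <- raw((.ceil8(nb) - nb))
  c(tag, payload, pad)
}

.w_numeric <- function(x, single = FALSE) {
  if (single)
    .w_el(7L, writeBin(as.numeric(x), raw(), size = 4, endian = "little"))
  else
    .w_el(9L, writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
}

.w_int32 <- function(x)
  .w_el(5L, writeBin(as.integer(x), raw(), size = 4, endian = "little"))

.w_matrix_raw <- function(value, name = "", single = FALSE) {
  flags <- .w_el(6L, writeBin(as.integer(c(.mat_class_of(value), 0L)),
                              raw(), size = 4, endian = "little"))
  body <- switch(as.character(.mat_class_of(value)),
    "6" = , "7" = {                             # numeric
      m <- if (is.matrix(value)) value else matrix(value, nrow = 1)
      c(.w_int32(dim(m)), .w_name(name), .w_numeric(as.numeric(m), single))
    },
    "4" = {                                     # char, stored as uint16
      codes <- utf8ToInt(value)
      c(.w_int32(c(1L, length(codes))), .w_name(name),
        .w_el(4L, writeBin(as.integer(codes), raw(), size = 2,
                           endian = "little")))
    },
    "2" = {                                     # struct (scalar or list-of)
      elems <- if (!is.null(names(value))) list(value) else value
      fields <- names(elems[[1]])
      flen <- 32L
      fn <- raw(flen * length(fields))
      for (i in seq_along(fields)) {
        b <- charToRaw(fields[i])
        fn[((i - 1L) * flen + 1L):((i - 1L) * flen + length(b))] <- b
      }
      payload <- c(.w_int32(c(1L, length(elems))), .w_name(name),
                   .w_el(5L, writeBin(flen, raw(), size = 4,
                                      endian = "little")),
                   .w_el(1L, fn))
      for (e in elems) for (f in fields)
        payload <- c(payload, .w_matrix_raw(e[[f]], "", single = single))
      payload
    },
    stop("unsupported value in MAT writer", call. = FALSE))
  .w_el(14L, c(flags, body))
}

.mat_class_of <- function(value) {
  if (is.character(value)) 4L
  else if (is.list(value)) 2L
  else 6L
}

.w_name <- function(name) .w_el(1L, charToRaw(name))

#' Write a recording as an EEGLAB-compatible .set file
#'
#' Emits an uncompressed MAT v5 file holding a continuous `EEG` structure
#' (nbchan, srate, pnts, trials, data, chanlocs with labels). The signal
#' matrix is stored in single precision inside the file, or in a
#' companion `.fdt` float32 file when `fdt = TRUE`, mirroring the two
#' layouts EEGLAB itself produces.
#'
#' @param rec an [eeg_recording].
#' @param path output `.set` path.
#' @param fdt store samples in a companion `.fdt` file instead of inline.
#' @return `path`, invisibly.
#' @export
write_set <- function(rec, path, fdt = FALSE) {
  stopifnot_recording(rec)
  chanlocs <- lapply(rec$channel_labels, function(l) list(labels = l))
  data_field <- if (fdt) {
    fdt_path <- sub("\\.set$", ".fdt", path)
    fcon <- file(fdt_path, "wb")
    writeBin(as.numeric(rec$data), fcon, size = 4, endian = "little")
    close(fcon)
    basename(fdt_path)
  } else rec$data
  EEG <- list(setname = rec$subject_id,
              nbchan = n_channels(rec),
              srate = rec$fs,
              pnts = n_samples(rec),
              trials = 1,
              xmin = 0,
              data = data_field,
              chanlocs = chanlocs)
  # header: 116-byte text, 8-byte subsys offset, version, endian mark
  txt <- charToRaw(sprintf("MATLAB 5.0 MAT-file, written by sinkindex on %s",
                           format(Sys.time(), "%Y-%m-%d")))
  hdr <- raw(128)
  hdr[seq_along(txt)] <- txt
  hdr[117:124] <- raw(8)
  hdr[125:126] <- writeBin(256L, raw(), size = 2, endian = "little")
  hdr[127:128] <- charToRaw("IM")
  body <- .w_matrix_raw(EEG, "EEG", single = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(body, con)
  invisible(path)
}
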