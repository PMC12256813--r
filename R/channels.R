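#' Canonical 19-channel 10-20 montage
#'
#' Channel names of the standard 19-electrode 10-20 scalp montage used
#' throughout the package, in the conventional acquisition order.
#'
#' @return Character vector of 19 channel labels.
#' @export
canonical_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "T3", "T4", "C3", "C4",
    "T5", "T6", "P3", "P4", "O1", "O2", "Fz", "Cz", "Pz")
}

# Aliases seen in the wild (modified combinatorial nomenclature etc.)
.channel_aliases <- c(
  T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6", FP1 = "Fp1", FP2 = "Fp2"
)

#' Map channel labels to canonical 10-20 names
#'
#' Case-insensitive mapping onto the canonical 19-channel label set, with
#' common aliases (T7/T8/P7/P8 for T3/T4/T5/T6) resolved. Labels with no
#' canonical counterpart are returned unchanged (extra channels are allowed;
#' they simply do not take part in region grouping).
#'
#' @param labels character vector of raw channel labels.
#' @return Character vector of the same length with canonical capitalization.
#' @export
canonicalize_channels <- function(labels) {
  labels <- trimws(labels)
  # strip common reference suffixes such as "Fp1-REF" or "EEG Fp1"
  labels <- sub("^EEG[ _]*", "", labels, ignore.case = TRUE)
  labels <- sub("-(REF|LE|AVG|A1|A2)$", "", labels, ignore.case = TRUE)
  canon <- canonical_channels()
  out <- labels
  for (i in seq_along(labels)) {
    up <- toupper(labels[i])
    hit <- match(up, toupper(canon))
    if (!is.na(hit)) {
      out[i] <- canon[hit]
    } else if (up %in% names(.channel_aliases)) {
      out[i] <- .channel_aliases[[up]]
    }
  }
  out
}

#' Frontal-temporal / central-parietal-occipital region scheme
#'
#' The electrode grouping used for regional sink-index averaging: a
#' frontal-temporal (FT) group of 8 electrodes and a central-parietal-
#' occipital (CPO) group of 11 electrodes. Fz is grouped with CPO,
#' following the source analysis convention this package reproduces.
#'
#' @param ft,cpo character vectors of channel labels. Defaults give the
#'   standard 8/11 split of the 19-channel montage.
#' @return Object of class `region_scheme`: list with `ft` and `cpo`.
#' @examples
#' region_scheme()
#' @export
region_scheme <- function(ft = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "T3", "T4"),
                          cpo = c("O1", "T5", "O2", "T6", "Cz", "Pz", "P3",
                                  "Fz", "P4", "C3", "C4")) {
  ft <- as.character(ft); cpo <- as.character(cpo)
  if (length(intersect(ft, cpo)) > 0L)
    stop("FT and CPO channel sets must be disjoint", call. = FALSE)
  structure(list(ft = ft, cpo = cpo), class = "region_scheme")
}

#' @export
print.region_scheme <- function(x, ...) {
  cat("Region scheme\n")
  cat("  FT  (", length(x$ft), "): ", paste(x$ft, collapse = ", "), "\n", sep = "")
  cat("  CPO (", length(x$cpo), "): ", paste(x$cpo, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' 2-D scalp coordinates for the 19-channel montage
#'
#' Standard top-view polar projection of the 10-20 positions onto the unit
#' disc (nose up, left ear on the left), used for topographic maps.
#'
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
electrode_coords <- function() {
  # (theta from +y axis, clockwise, degrees; r in [0, 1])
  pos <- rbind(
    Fp1 = c(-18, 0.95), Fp2 = c(18, 0.95),
    F7  = c(-54, 0.95), F8  = c(54, 0.95),
    F3  = c(-39, 0.56), F4  = c(39, 0.56),
    Fz  = c(0, 0.48),
    T3  = c(-90, 0.95), T4  = c(90, 0.95),
    C3  = c(-90, 0.48), C4  = c(90, 0.48),
    Cz  = c(0, 0),
    T5  = c(-126, 0.95), T6  = c(126, 0.95),
    P3  = c(-141, 0.56), P4  = c(141, 0.56),
    Pz  = c(180, 0.48),
    O1  = c(-162, 0.95), O2  = c(162, 0.95)
  )
  th <- pos[, 1] * pi / 180
  data.frame(channel = rownames(pos),
             x = pos[, 2] * sin(th),
             y = pos[, 2] * cos(th),
             row.names = NULL, stringsAsFactors = FALSE)
}
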