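#' Row and column 2-norms of a transition matrix
#'
#' The "size" of each row and column of a state-transition matrix: the
#' Euclidean norm over all N entries, diagonal included. A sink channel
#' has a large row size (strongly driven) and a small column size (drives
#' little); a source channel the reverse.
#'
#' @param A square numeric matrix.
#' @return List with numeric vectors `row_sizes` and `col_sizes`.
#' @examples
#' row_col_norms(diag(4))
#' @export
row_col_norms <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A))
    stop("shape error: transition matrix must be square", call. = FALSE)
  list(row_sizes = sqrt(rowSums(A^2)), col_sizes = sqrt(colSums(A^2)))
}

#' Normalized ranks of a vector
#'
#' Ranks with 1 = smallest and N = largest, divided by N, so the output
#' takes values in \{1/N, ..., 1\}. Ties are broken by first-occurrence
#' order, which keeps the result a deterministic permutation of that grid.
#'
#' @param values finite numeric vector, length >= 2.
#' @return Numeric vector of normalized ranks in (0, 1].
#' @examples
#' normalized_ranks(c(3, 1, 2))  # 1, 1/3, 2/3
#' @export
normalized_ranks <- function(values) {
  if (anyNA(values) || any(!is.finite(values)))
    stop("validation error: non-finite values in rank input", call. = FALSE)
  N <- length(values)
  if (N < 2L) stop("need at least 2 values to rank", call. = FALSE)
  rank(values, ties.method = "first") / N
}

#' Per-channel sink index of one transition matrix
#'
#' Distance-to-ideal-sink score. Row and column sizes are rank-normalized
#' onto \{1/N, ..., 1\}; the ideal sink sits at (rr, cr) = (1, 1/N) —
#' maximal row rank, minimal column rank — and each channel scores
#' `c - || (rr_i, cr_i) - (1, 1/N) ||`. With the default constant
#' `c = sqrt(2)` the attainable range is `[sqrt(2)/N, sqrt(2)]`.
#'
#' @param A square numeric matrix (N >= 2).
#' @param eq2_constant additive constant `c`; default `sqrt(2)`.
#' @return Numeric vector of N sink indices (named if A has dimnames).
#' @examples
#' sink_index_of_matrix(rbind(c(0, 0), c(0.9, 0)))  # node 2 is an ideal sink
#' @export
sink_index_of_matrix <- function(A, eq2_constant = sqrt(2)) {
  ns <- row_col_norms(A)
  N <- length(ns$row_sizes)
  if (N < 2L) stop("need at least a 2-channel network", call. = FALSE)
  rr <- normalized_ranks(ns$row_sizes)
  cr <- normalized_ranks(ns$col_sizes)
  si <- eq2_constant - sqrt((rr - 1)^2 + (cr - 1 / N)^2)
  names(si) <- rownames(A)
  si
}

#' Sink map of a dynamic network model
#'
#' Computes the per-channel sink index for every valid window of a fitted
#' DNM, together with the underlying normalized row/column ranks and the
#' per-channel average over all valid windows of the recording.
#'
#' @param dnm a [fit_dnm()] fit.
#' @param eq2_constant additive constant of the sink-index formula.
#' @return Object of class `sink_map`: list with `si`, `rr_rank`,
#'   `cr_rank` (channels x windows matrices, skipped windows NA),
#'   `time_avg_si` (per-channel vector), `channel_labels`, `window_s`
#'   (window start times in seconds), `eq2_constant`.
#' @examples
#' rec <- simulate_recording(planted_network(N = 5, seed = 1), duration_s = 4)
#' sm <- sink_map(fit_dnm(rec))
#' sm$time_avg_si
#' @export
sink_map <- function(dnm, eq2_constant = sqrt(2)) {
  if (!inherits(dnm, "dnm")) stop("expected a 'dnm' fit", call. = FALSE)
  if (!any(dnm$valid))
    stop("empty model: no valid windows to map", call. = FALSE)
  N <- length(dnm$channel_labels)
  M <- dnm$n_windows
  si <- rr <- cr <- matrix(NA_real_, N, M,
                           dimnames = list(dnm$channel_labels, NULL))
  for (k in which(dnm$valid)) {
    ns <- row_col_norms(dnm$A_seq[[k]])
    rr[, k] <- normalized_ranks(ns$row_sizes)
    cr[, k] <- normalized_ranks(ns$col_sizes)
    si[, k] <- eq2_constant - sqrt((rr[, k] - 1)^2 + (cr[, k] - 1 / N)^2)
  }
  structure(
    list(si = si, rr_rank = rr, cr_rank = cr,
         time_avg_si = rowMeans(si, na.rm = TRUE),
         channel_labels = dnm$channel_labels,
         window_s = (seq_len(M) - 1L) * dnm$window_len_samples / dnm$fs,
         eq2_constant = eq2_constant,
         subject_id = dnm$subject_id),
    class = "sink_map"
  )
}

#' @export
print.sink_map <- function(x, ...) {
  cat("<sink_map> subject:", x$subject_id, "\n")
  cat(sprintf("  %d channels x %d windows; sink index in [%.3f, %.3f]\n",
              nrow(x$si), ncol(x$si), min(x$si, na.rm = TRUE),
              max(x$si, na.rm = TRUE)))
  cat("  time-averaged SI:\n")
  print(round(x$time_avg_si, 3))
  invisible(x)
}

#' Heatmap of a sink map
#'
#' @param x a [sink_map()].
#' @param col color palette.
#' @param ... passed to [graphics::image()].
#' @export
plot.sink_map <- function(x, col = grDevices::hcl.colors(64, "YlOrRd",
                                                         rev = TRUE), ...) {
  keep <- colSums(is.na(x$si)) == 0
  z <- t(x$si[, keep, drop = FALSE])
  graphics::image(x = x$window_s[keep], y = seq_len(nrow(x$si)), z = z,
                  col = col, xlab = "time (s)", ylab = "",
                  yaxt = "n", main = paste("Sink index:", x$subject_id), ...)
  graphics::axis(2, at = seq_len(nrow(x$si)), labels = x$channel_labels,
                 las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Regional sink-index marker for one subject
#'
#' Averages the time-averaged sink index over the FT and CPO electrode
#' groups and forms the FT/CPO ratio — the headline scalar marker.
#'
#' @param sink_map a [sink_map()].
#' @param scheme a [region_scheme()]; must jointly cover every channel of
#'   the map.
#' @return data.frame row with `subject_id`, `si_ft`, `si_cpo`, `si_ratio`.
#' @export
subject_marker <- function(sink_map, scheme = region_scheme()) {
  if (!inherits(sink_map, "sink_map")) stop("expected a 'sink_map'", call. = FALSE)
  chans <- sink_map$channel_labels
  missing <- setdiff(chans, c(scheme$ft, scheme$cpo))
  if (length(missing) > 0)
    stop("validation error: region scheme misses channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ft <- intersect(scheme$ft, chans)
  cpo <- intersect(scheme$cpo, chans)
  if (length(ft) == 0 || length(cpo) == 0)
    stop("validation error: a region has no channels in this recording",
         call. = FALSE)
  si_ft <- mean(sink_map$time_avg_si[ft])
  si_cpo <- mean(sink_map$time_avg_si[cpo])
  if (si_cpo == 0) stop("division error: CPO mean sink index is zero",
                        call. = FALSE)
  data.frame(subject_id = sink_map$subject_id, si_ft = si_ft,
             si_cpo = si_cpo, si_ratio = si_ft / si_cpo,
             stringsAsFactors = FALSE)
}

#' Attainable sink-index range for an N-channel network
#'
#' Enumerates every normalized (row rank, column rank) pair on the
#' \{1/N, ..., 1\}^2 grid and evaluates the sink-index formula, returning
#' the attainable extremes. Used to verify the closed-form bounds
#' `[c - sqrt(2) (1 - 1/N), c]`.
#'
#' @param N number of channels.
#' @param eq2_constant additive constant of the formula.
#' @return List with `min`, `max` and the full `grid` (data.frame with
#'   rr, cr, si).
#' @examples
#' sink_index_range(19)  # c(0.0744, 1.4142) to 4 decimals
#' @export
sink_index_range <- function(N = 19, eq2_constant = sqrt(2)) {
  ranks <- seq_len(N) / N
  grid <- expand.grid(rr = ranks, cr = ranks)
  grid$si <- eq2_constant - sqrt((grid$rr - 1)^2 + (grid$cr - 1 / N)^2)
  list(min = min(grid$si), max = max(grid$si), grid = grid)
}
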