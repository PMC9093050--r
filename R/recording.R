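#' Multichannel EEG recording
#'
#' The container every stage of the pipeline operates on: a channels x samples
#' matrix of potentials (microvolts) plus the sampling rate, channel labels,
#' the list of continuity segments, and a reference flag. Continuity segments
#' are half-open 0-based sample intervals `[start, end)`; artifact-removal cut
#' points break continuity and every filtering / windowing stage respects them.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of unique channel names; defaults to the
#'   rownames of `data` or `"CH1"..."CHn"`.
#' @param segments list of length-2 numeric vectors `c(start, end)` (0-based,
#'   half-open, in samples), or `NULL` for one segment spanning all samples.
#' @param reference one of `"original"`, `"common_average"`, `"laplacian"`.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = NULL,
                          segments = NULL,
                          reference = c("original", "common_average", "laplacian")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(labels)) {
    labels <- rownames(data)
    if (is.null(labels)) labels <- paste0("CH", seq_len(nrow(data)))
  }
  if (length(labels) != nrow(data)) {
    stop("`labels` length must equal the number of rows (channels) of `data`")
  }
  if (anyDuplicated(labels)) stop("duplicate channel labels")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar")
  n <- ncol(data)
  if (is.null(segments)) segments <- list(c(0, n))
  segments <- lapply(segments, function(s) as.integer(round(s)))
  seg <- do.call(rbind, segments)
  if (ncol(seg) != 2L) stop("each segment must be c(start, end)")
  if (any(seg[, 1] < 0) || any(seg[, 2] > n) || any(seg[, 1] >= seg[, 2])) {
    stop("segments must be non-empty half-open intervals within [0, samples)")
  }
  o <- order(seg[, 1])
  seg <- seg[o, , drop = FALSE]
  if (nrow(seg) > 1L && any(seg[-1L, 1] < seg[-nrow(seg), 2])) {
    stop("segments must be disjoint")
  }
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels,
         segments = lapply(seq_len(nrow(seg)), function(i) seg[i, ]),
         reference = reference),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s reference, %d segment%s)\n",
              n_channels(x), n_samples(x), x$fs, x$reference,
              length(x$segments), if (length(x$segments) == 1L) "" else "s"))
  invisible(x)
}

#' @rdname eeg_recording
#' @param rec an `eeg_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname eeg_recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Duration of the analyzed (in-segment) signal, in seconds
#' @param rec an `eeg_recording`.
#' @export
segment_seconds <- function(rec) {
  sum(vapply(rec$segments, function(s) s[2] - s[1], numeric(1))) / rec$fs
}

# 1-based R column indices of one 0-based half-open segment
seg_idx <- function(s) (s[1] + 1L):s[2]
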