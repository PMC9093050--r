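# FFT-based analytic signal (Hilbert transform) of one real vector
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Band-limited instantaneous phase, tiled into epochs
#'
#' Band-pass FIR (hamming window, order = 3 cycles of the band's low edge),
#' analytic signal per continuity segment, then a fraction of each segment's
#' phase signal is discarded on each side to eliminate filter/Hilbert edge
#' effects before tiling non-overlapping epochs. Epochs never span a
#' continuity break; a leftover tail shorter than one epoch is dropped.
#'
#' @param rec a Laplacian-referenced [eeg_recording()].
#' @param band length-2 numeric `c(low, high)` in Hz, or a band name from
#'   [connectivity_bands()].
#' @param epoch_s epoch length in seconds (default 2).
#' @param edge_trim fraction of each segment discarded per side (default 0.10).
#' @return An `epoched_phase`: array `phases` (epochs x channels x samples,
#'   radians in (-pi, pi]), plus `band`, `epoch_s`, `labels`, `fs`.
#' @export
extract_phase <- function(rec, band, epoch_s = 2, edge_trim = 0.10) {
  if (rec$reference == "original")
    warning("extract_phase expects a re-referenced (Laplacian) recording")
  band_name <- NA_character_
  if (is.character(band)) {
    cb <- connectivity_bands()
    i <- match(band, cb$band)
    if (is.na(i)) stop("unknown connectivity band: ", band)
    band_name <- band
    band <- c(cb$low[i], cb$high[i])
  }
  if (band[1] <= 0 || band[2] >= rec$fs / 2) stop("band must lie inside (0, fs/2)")
  order <- ceiling(3 * rec$fs / band[1] / 2) * 2   # 3 cycles of the low edge, even
  b <- fir_coefficients(fir_spec("bandpass", order = order, cutoff = band), rec$fs)
  ne <- round(epoch_s * rec$fs)
  epochs <- list()
  for (s in rec$segments) {
    len <- s[2] - s[1]
    if (len <= 3 * order)
      stop("continuity segment too short for the band-pass filter")
    idx <- seg_idx(s)
    filt <- t(apply(rec$data[, idx, drop = FALSE], 1L,
                    function(x) zero_phase_filter(b, x)))
    ph <- t(apply(filt, 1L, function(x) Arg(analytic_signal(x))))
    trim <- floor(len * edge_trim)
    usable <- if (len - 2 * trim >= 1) ph[, (trim + 1):(len - trim), drop = FALSE]
              else ph[, 0, drop = FALSE]
    n_ep <- ncol(usable) %/% ne
    for (m in seq_len(n_ep)) {
      epochs[[length(epochs) + 1L]] <- usable[, ((m - 1) * ne + 1):(m * ne), drop = FALSE]
    }
  }
  if (!length(epochs)) stop("no trimmed segment is long enough for one epoch")
  phases <- array(0, dim = c(length(epochs), n_channels(rec), ne))
  for (m in seq_along(epochs)) phases[m, , ] <- epochs[[m]]
  structure(list(phases = phases, band = band, band_name = band_name,
                 epoch_s = epoch_s, labels = rec$labels, fs = rec$fs),
            class = "epoched_phase")
}

#' Phase-locking value matrix
#'
#' For channels i and j, each epoch contributes the magnitude of the mean
#' phase-difference phasor over the epoch's samples; the PLV is the average of
#' those magnitudes over epochs. Values lie in `[0, 1]`; the diagonal is 1.
#'
#' @param phase an [extract_phase()] result with M >= 1 epochs of N >= 2
#'   samples.
#' @return A `connectivity_matrix`: symmetric channels x channels matrix
#'   `values` plus `band`, `labels`.
#' @export
plv <- function(phase) {
  d <- dim(phase$phases)
  M <- d[1]; C <- d[2]; N <- d[3]
  if (N < 2) stop("epochs must contain at least 2 samples")
  acc <- matrix(0, C, C)
  for (m in seq_len(M)) {
    Z <- exp(1i * phase$phases[m, , , drop = TRUE])
    if (is.null(dim(Z))) Z <- matrix(Z, nrow = C)
    S <- Z %*% Conj(t(Z))          # S[i, j] = sum_n e^{i(phi_i - phi_j)}
    acc <- acc + Mod(S) / N
  }
  values <- acc / M
  diag(values) <- 1
  dimnames(values) <- list(phase$labels, phase$labels)
  structure(list(values = values, band = phase$band_name, labels = phase$labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d channels, band %s\n",
              length(x$labels),
              if (is.na(x$band)) "(custom)" else x$band))
  invisible(x)
}

#' Band-limited PLV connectivity of a recording
#'
#' Convenience wrapper: [extract_phase()] then [plv()].
#' @inheritParams extract_phase
#' @return A `connectivity_matrix`.
#' @export
band_plv <- function(rec, band, epoch_s = 2, edge_trim = 0.10) {
  plv(extract_phase(rec, band, epoch_s = epoch_s, edge_trim = edge_trim))
}

#' Mean functional connectivity strength over a connected component (FCSCC)
#'
#' The arithmetic mean of the connectivity values over the edges of a
#' (statistically identified) connected component.
#'
#' @param conn a `connectivity_matrix`.
#' @param component a two-column matrix or data frame of edges, as channel
#'   labels or integer indices.
#' @return A scalar.
#' @export
mean_fcscc <- function(conn, component) {
  component <- as.matrix(component)
  if (nrow(component) == 0) stop("empty component")
  if (is.character(component)) {
    i <- match(component[, 1], conn$labels)
    j <- match(component[, 2], conn$labels)
    if (anyNA(i) || anyNA(j)) stop("component edge labels not in the matrix")
  } else {
    i <- as.integer(component[, 1]); j <- as.integer(component[, 2])
  }
  mean(conn$values[cbind(i, j)])
}

#' All undirected edges of a connectivity matrix
#' @param conn a `connectivity_matrix`.
#' @return Two-column integer matrix of the `n(n-1)/2` undirected pairs.
#' @export
all_edges <- function(conn) {
  n <- length(conn$labels)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  cbind(i = idx[, 1], j = idx[, 2])
}
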