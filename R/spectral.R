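#' Welch power spectral density
#'
#' Hamming-tapered, 50%-overlapping averaged periodograms computed per
#' continuity segment: windows never span a segment break, so artifact-removal
#' cut points cannot contaminate the spectrum. With 2-s windows at 250 Hz the
#' frequency resolution is 0.5 Hz.
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length in seconds (default 2).
#' @param overlap fractional overlap between consecutive windows (default 0.5).
#' @return A `psd_estimate`: list with `freqs` (Hz), `psd` (channels x freqs,
#'   power density), `n_windows`, `labels`, `fs`.
#' @export
welch_psd <- function(rec, window_s = 2, overlap = 0.5) {
  nw <- round(window_s * rec$fs)
  hop <- max(1L, round(nw * (1 - overlap)))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  scale <- 1 / (rec$fs * sum(w^2))
  n_freq <- nw %/% 2 + 1
  freqs <- (0:(n_freq - 1)) * rec$fs / nw
  acc <- matrix(0, nrow = n_channels(rec), ncol = n_freq)
  n_windows <- 0L
  for (s in rec$segments) {
    if ((s[2] - s[1]) < nw) next
    starts <- seq(s[1], s[2] - nw, by = hop)
    for (st in starts) {
      x <- rec$data[, (st + 1):(st + nw), drop = FALSE]
      x <- sweep(x, 1L, rowMeans(x))                 # constant detrend
      xt <- sweep(x, 2L, w, `*`)
      X <- t(apply(xt, 1L, stats::fft))
      p <- (Mod(X[, seq_len(n_freq), drop = FALSE])^2) * scale
      # one-sided: double everything except DC (and Nyquist when nw is even)
      dbl <- rep(2, n_freq); dbl[1] <- 1
      if (nw %% 2 == 0) dbl[n_freq] <- 1
      acc <- acc + sweep(p, 2L, dbl, `*`)
      n_windows <- n_windows + 1L
    }
  }
  if (n_windows == 0L) stop("no full window fits inside any continuity segment")
  structure(list(freqs = freqs, psd = acc / n_windows, n_windows = n_windows,
                 labels = rec$labels, fs = rec$fs),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d channels, %g-%g Hz @ %g Hz resolution, %d windows\n",
              length(x$labels), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$n_windows))
  invisible(x)
}

band_bins <- function(freqs, low, high, tol = 1e-9) {
  which(freqs >= low - tol & freqs <= high + tol)
}

#' Relative band power
#'
#' Channel-level relative power is the summed PSD over a band's (inclusive)
#' bins divided by the summed PSD over the scheme's total range (1-42 Hz by
#' default); the global value per band averages the channel fractions across
#' channels; the global relative PSD is the channel-mean PSD normalized to sum
#' to one over the total range.
#'
#' @param psd a [welch_psd()] estimate.
#' @param scheme a [band_scheme()] (bin edges must align with the PSD grid).
#' @return A list with tibbles `channel` (channel, band, relative_power),
#'   `global` (band, relative_power) and `global_rel_psd` (freq, value).
#' @export
relative_power <- function(psd, scheme = spectral_bands()) {
  tot <- attr(scheme, "total_range")
  tot_bins <- band_bins(psd$freqs, tot[1], tot[2])
  denom <- rowSums(psd$psd[, tot_bins, drop = FALSE])
  if (any(denom <= 0)) stop("zero total power inside the total range")
  per_band <- lapply(seq_len(nrow(scheme)), function(i) {
    bins <- band_bins(psd$freqs, scheme$low[i], scheme$high[i])
    tibble::tibble(channel = psd$labels, band = scheme$band[i],
                   relative_power = rowSums(psd$psd[, bins, drop = FALSE]) / denom)
  })
  channel <- dplyr::bind_rows(per_band)
  global <- channel |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(relative_power = mean(.data$relative_power), .groups = "drop") |>
    dplyr::arrange(match(.data$band, scheme$band))
  mean_psd <- colMeans(psd$psd)
  grp <- tibble::tibble(freq = psd$freqs[tot_bins],
                        value = mean_psd[tot_bins] / sum(mean_psd[tot_bins]))
  list(channel = channel, global = global, global_rel_psd = grp)
}

#' Brain symmetry indices (pdBSI and rBSI)
#'
#' Both indices measure normalized left-right spectral asymmetry per band from
#' the bin-level quantity |(R - L) / (R + L)| of the PSD. pdBSI evaluates it
#' per homologous channel pair and averages across pairs and bins; rBSI first
#' averages the PSD over each hemisphere and then evaluates the asymmetry per
#' bin. Midline channels are excluded; bins with R + L = 0 are skipped.
#'
#' @param psd a [welch_psd()] estimate.
#' @param montage an [eeg_montage()] whose pairing covers the PSD channels.
#' @param scheme a [band_scheme()].
#' @return A tibble with columns `band`, `pdBSI`, `rBSI` (both in `[0, 1]`).
#' @export
symmetry_indices <- function(psd, montage, scheme = spectral_bands()) {
  pairs <- montage$homologous_pairs
  pairs <- pairs[pairs$left %in% psd$labels & pairs$right %in% psd$labels, ]
  if (!nrow(pairs)) stop("montage pairing covers no PSD channels")
  L <- psd$psd[match(pairs$left, psd$labels), , drop = FALSE]
  R <- psd$psd[match(pairs$right, psd$labels), , drop = FALSE]
  res <- lapply(seq_len(nrow(scheme)), function(i) {
    bins <- band_bins(psd$freqs, scheme$low[i], scheme$high[i])
    l <- L[, bins, drop = FALSE]; r <- R[, bins, drop = FALSE]
    s <- r + l
    ratio <- abs(r - l) / s
    ok <- s > 0
    if (!any(ok)) stop("all bins have zero power in band ", scheme$band[i])
    pd <- mean(ratio[ok])
    lbar <- colMeans(l); rbar <- colMeans(r)
    sb <- rbar + lbar
    okb <- sb > 0
    rb <- mean(abs(rbar[okb] - lbar[okb]) / sb[okb])
    tibble::tibble(band = scheme$band[i], pdBSI = pd, rBSI = rb)
  })
  dplyr::bind_rows(res)
}
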