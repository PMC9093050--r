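#' Hamming-window FIR filter specification
#'
#' Linear-phase type-I FIR designs (even order, hamming window) specified by
#' their order, transition width and -6 dB cutoff, matching the window-method
#' convention where the specified cutoff is the half-amplitude point.
#'
#' @param kind `"lowpass"`, `"highpass"` or `"bandpass"`.
#' @param order filter order (taps - 1), must be even.
#' @param cutoff -6 dB cutoff in Hz (length 2 for bandpass).
#' @param transition transition width in Hz (metadata; implied by the order).
#' @return A `fir_spec` object.
#' @export
fir_spec <- function(kind = c("lowpass", "highpass", "bandpass"),
                     order, cutoff, transition = NA_real_) {
  kind <- match.arg(kind)
  if (order %% 2 != 0) stop("`order` must be even for a linear-phase type-I FIR")
  if (kind == "bandpass" && length(cutoff) != 2) stop("bandpass needs two cutoffs")
  if (kind != "bandpass" && length(cutoff) != 1) stop("need one cutoff")
  structure(list(kind = kind, order = as.integer(order),
                 cutoff = as.numeric(cutoff), transition = transition,
                 window = "hamming"),
            class = "fir_spec")
}

#' Default preprocessing filters
#'
#' The pipeline's anti-alias low-pass (order 660, transition 5 Hz, -6 dB
#' cutoff 45 Hz, applied at the acquisition rate) and the post-resampling
#' high-pass (order 826, transition 1 Hz, -6 dB cutoff 0.5 Hz).
#' @name default_filters
NULL

#' @rdname default_filters
#' @export
default_lowpass <- function() fir_spec("lowpass", order = 660, cutoff = 45, transition = 5)

#' @rdname default_filters
#' @export
default_highpass <- function() fir_spec("highpass", order = 826, cutoff = 0.5, transition = 1)

# windowed-sinc design (hamming); the specified cutoff is the -6 dB
# (half-amplitude) point, the convention of the referenced design family
fir_coefficients <- function(spec, fs) {
  nyq <- fs / 2
  if (any(spec$cutoff <= 0) || any(spec$cutoff >= nyq))
    stop("cutoff must lie strictly inside (0, fs/2)")
  n_taps <- spec$order + 1L
  m <- (0:(n_taps - 1)) - spec$order / 2
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  ideal_lp <- function(fc) 2 * fc / fs * sinc(2 * fc / fs * m)
  h <- switch(spec$kind,
              lowpass = ideal_lp(spec$cutoff),
              highpass = as.numeric(m == 0) - ideal_lp(spec$cutoff),
              bandpass = ideal_lp(spec$cutoff[2]) - ideal_lp(spec$cutoff[1]))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n_taps - 1)) / spec$order)
  h <- h * w
  # unit gain at the passband's reference frequency
  f_ref <- switch(spec$kind,
                  lowpass = 0,
                  highpass = nyq,
                  bandpass = mean(spec$cutoff))
  gain <- abs(sum(h * exp(-2i * pi * f_ref / fs * (0:(n_taps - 1)))))
  h / gain
}

# zero-phase filtering of one vector: causal FIR then group-delay compensation
zero_phase_filter <- function(b, x) {
  d <- (length(b) - 1) %/% 2
  y <- signal::filter(b, 1, c(x, numeric(d)))
  as.numeric(y[(d + 1):(d + length(x))])
}

#' Apply a zero-phase FIR filter per continuity segment
#'
#' The causal linear-phase FIR is applied to each channel of each continuity
#' segment independently and its group delay compensated, so the output is
#' zero-phase and artifact-cut discontinuities never leak across segments.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [fir_spec()].
#' @return The filtered recording (same shape).
#' @export
fir_filter <- function(rec, spec) {
  b <- fir_coefficients(spec, rec$fs)
  too_short <- vapply(rec$segments, function(s) (s[2] - s[1]) <= 3 * spec$order, logical(1))
  if (any(too_short))
    stop("continuity segment shorter than 3 x filter order (", spec$order, " taps)")
  for (s in rec$segments) {
    idx <- seg_idx(s)
    rec$data[, idx] <- t(apply(rec$data[, idx, drop = FALSE], 1L,
                               function(x) zero_phase_filter(b, x)))
  }
  rec
}

#' Resample a recording
#'
#' Sample counts and segment boundaries are rescaled by `fs_new/fs` (floor).
#' Integer downsampling takes every k-th sample (anti-alias filtering is the
#' caller's responsibility, see [default_lowpass()]); non-integer ratios use
#' linear interpolation onto the new time grid.
#'
#' @param rec an [eeg_recording()].
#' @param fs_new target sampling rate in Hz.
#' @return The resampled recording.
#' @export
resample_recording <- function(rec, fs_new) {
  if (fs_new <= 0) stop("`fs_new` must be positive")
  if (fs_new == rec$fs) return(rec)
  ratio <- fs_new / rec$fs
  segs_new <- lapply(rec$segments, function(s) floor(s * ratio))
  segs_new <- Filter(function(s) s[2] > s[1], segs_new)
  if (!length(segs_new)) stop("no segment survives resampling")
  n_new <- floor(n_samples(rec) * ratio)
  if (rec$fs %% fs_new == 0) {
    k <- rec$fs / fs_new
    data <- rec$data[, seq(1, by = k, length.out = n_new), drop = FALSE]
  } else {
    t_old <- (seq_len(n_samples(rec)) - 1) / rec$fs
    t_new <- (seq_len(n_new) - 1) / fs_new
    data <- t(apply(rec$data, 1L, function(x) {
      stats::approx(t_old, x, xout = t_new, rule = 2)$y
    }))
  }
  eeg_recording(data, fs = fs_new, labels = rec$labels, segments = segs_new,
                reference = rec$reference)
}

#' Re-reference to the common average
#'
#' Subtracts the per-sample channel mean so every column of the data matrix
#' sums to zero.
#'
#' @param rec an [eeg_recording()].
#' @return The re-referenced recording with `reference = "common_average"`.
#' @export
rereference_average <- function(rec) {
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec$reference <- "common_average"
  rec
}

#' Full deterministic preprocessing pipeline
#'
#' Anti-alias low-pass at the acquisition rate, downsample to `fs_target`,
#' high-pass, optional bad-channel spherical interpolation, then common-average
#' re-referencing. Bad channels are caller-supplied (their detection is a
#' manual step outside this package).
#'
#' @param rec an [eeg_recording()].
#' @param montage an [eeg_montage()] (needed when `bad` is non-empty).
#' @param bad labels of bad channels to interpolate.
#' @param fs_target target sampling rate (Hz).
#' @param lowpass,highpass [fir_spec()] objects.
#' @return The preprocessed recording.
#' @export
preprocess_recording <- function(rec, montage = NULL, bad = character(),
                                 fs_target = 250,
                                 lowpass = default_lowpass(),
                                 highpass = default_highpass()) {
  rec <- fir_filter(rec, lowpass)
  if (fs_target < rec$fs) rec <- resample_recording(rec, fs_target)
  rec <- fir_filter(rec, highpass)
  if (length(bad)) {
    if (is.null(montage)) stop("`montage` required to interpolate bad channels")
    rec <- interpolate_channels(rec, bad, montage)
  }
  rereference_average(rec)
}
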