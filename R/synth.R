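# narrowband unit-variance noise: hamming-FIR band-passed white noise with a
# ~2 Hz transition so band leakage stays small even for the high bands
narrowband_noise <- function(n, band, fs, order = NULL) {
  if (is.null(order)) order <- min(ceiling(3.3 * fs / 2 / 2) * 2, floor((n - 1) / 3 / 2) * 2)
  b <- fir_coefficients(fir_spec("bandpass", order = order, cutoff = band), fs)
  x <- zero_phase_filter(b, stats::rnorm(n))
  x / stats::sd(x)
}

#' Generate band-structured oscillatory EEG with planted phase coupling
#'
#' Each channel is a sum over the five primary connectivity bands of
#' amplitude-scaled narrowband noise (band-pass filtered white noise, not
#' sinusoids, so spectral and Hilbert stages face realistic signals). Per-band
#' relative power follows `band_power`; coupling is planted by mixing a shared
#' narrowband source into both channels of a pair with weight equal to the
#' coupling strength, which makes the band PLV monotone in that strength.
#'
#' @param band_power named numeric over the five primary bands (delta, theta,
#'   alpha, beta, gamma), summing to 1, or a channels x 5 matrix of per-channel
#'   targets.
#' @param coupling optional data frame with columns `chan1`, `chan2`, `band`,
#'   `strength` (in `[0, 1]`).
#' @param duration_s recording length in seconds (default 60).
#' @param fs sampling rate (default 250 Hz).
#' @param labels channel labels (default `"CH1"..."CH8"`).
#' @param rereference subtract the common average before returning
#'   (default TRUE).
#' @param seed integer seed; the same seed yields bit-identical output.
#' @return An [eeg_recording()].
#' @export
gen_oscillatory <- function(band_power, coupling = NULL, duration_s = 60,
                            fs = 250, labels = paste0("CH", 1:8),
                            rereference = TRUE, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  bands <- connectivity_bands()
  nb <- nrow(bands)
  n_ch <- length(labels)
  if (is.null(dim(band_power))) {
    band_power <- band_power[bands$band]
    if (anyNA(band_power)) stop("`band_power` must name the five primary bands")
    band_power <- matrix(band_power, nrow = n_ch, ncol = nb, byrow = TRUE,
                         dimnames = list(labels, bands$band))
  }
  if (any(abs(rowSums(band_power) - 1) > 1e-6))
    stop("relative power targets must sum to 1 over the five primary bands")
  n <- round(duration_s * fs)
  if (duration_s < 3 / bands$low[1])
    stop("duration too short for 3 cycles of the lowest band")
  if (!is.null(coupling)) {
    stopifnot(all(c("chan1", "chan2", "band", "strength") %in% names(coupling)))
    if (any(coupling$strength < 0 | coupling$strength > 1))
      stop("coupling strengths must lie in [0, 1]")
  }
  data <- matrix(0, n_ch, n, dimnames = list(labels, NULL))
  for (bi in seq_len(nb)) {
    band <- c(bands$low[bi], bands$high[bi])
    has_coupling <- !is.null(coupling) && any(coupling$band == bands$band[bi])
    if (all(band_power[, bi] == 0) && !has_coupling) next
    comp <- t(vapply(seq_len(n_ch), function(ch) narrowband_noise(n, band, fs),
                     numeric(n)))
    if (!is.null(coupling)) {
      sel <- coupling$band == bands$band[bi]
      cpl <- coupling[sel, , drop = FALSE]
      # rows sharing a `source` id draw one common narrowband source, so a
      # whole subnetwork (clique) can be coupled coherently; by default each
      # row is its own source (plain pairwise coupling)
      src <- if ("source" %in% names(cpl)) cpl$source else seq_len(nrow(cpl))
      for (g in unique(src)) {
        rows <- cpl[src == g, , drop = FALSE]
        chans <- unique(c(rows$chan1, rows$chan2))
        idx <- match(chans, labels)
        if (anyNA(idx)) stop("coupling names unknown channel")
        shared <- narrowband_noise(n, band, fs)
        for (ci in seq_along(chans)) {
          s <- max(rows$strength[rows$chan1 == chans[ci] |
                                 rows$chan2 == chans[ci]])
          comp[idx[ci], ] <- sqrt(1 - s) * comp[idx[ci], ] + sqrt(s) * shared
        }
      }
    }
    data <- data + sqrt(band_power[, bi]) * comp
  }
  rec <- eeg_recording(data, fs = fs, labels = labels)
  if (rereference) rec <- rereference_average(rec)
  rec
}

# smooth random average-referenced unit-norm maps with bounded pairwise |corr|
random_templates <- function(K, positions, max_abs_corr = 0.95, max_tries = 200) {
  C <- nrow(positions)
  basis <- cbind(positions,
                 positions[, 1] * positions[, 2],
                 positions[, 1] * positions[, 3],
                 positions[, 2] * positions[, 3],
                 positions[, 1]^2 - positions[, 3]^2)
  for (try in seq_len(max_tries)) {
    W <- matrix(stats::rnorm(ncol(basis) * K), ncol(basis), K)
    maps <- basis %*% W
    maps <- sweep(maps, 2L, colMeans(maps))
    maps <- sweep(maps, 2L, sqrt(colSums(maps^2)), `/`)
    cors <- abs(spatial_corr_matrix(maps, maps))
    diag(cors) <- 0
    if (max(cors) < max_abs_corr) return(t(maps))
  }
  stop("could not draw sufficiently distinct templates")
}

#' Generate microstate-switching EEG with known ground truth
#'
#' The signal is a sequence of quasi-stable topographies: at each sample the
#' active template (drawn from a semi-Markov sequence with gamma-distributed
#' segment durations, no immediate self-transitions) is scaled by a positive
#' amplitude envelope (rectified alpha-band noise, so GFP shows realistic
#' peaks) and spatially white Gaussian noise is added at the requested SNR
#' (signal RMS / noise RMS). The recording is common-average re-referenced.
#'
#' @param K number of template classes (>= 2).
#' @param mean_dur_ms mean segment duration in ms (>= 40).
#' @param snr signal-to-noise amplitude ratio (> 0); `Inf` for noiseless.
#' @param duration_s recording length in seconds.
#' @param fs sampling rate (Hz).
#' @param montage an [eeg_montage()] supplying channel geometry (default: the
#'   packaged 59-channel montage).
#' @param min_dur_ms hard floor on generated segment durations.
#' @param templates optional K x channels matrix of ground-truth templates to
#'   reuse (e.g., to generate several recordings of one "study"); defaults
#'   to fresh random smooth maps.
#' @param seed integer seed.
#' @return List with `recording` (an [eeg_recording()]) and `truth` (list:
#'   `templates` K x channels, `label_sequence`, `segment_durations_ms`,
#'   `envelope`).
#' @export
gen_microstate_eeg <- function(K = 4, mean_dur_ms = 100, snr = 5,
                               duration_s = 30, fs = 250,
                               montage = default_montage(),
                               min_dur_ms = 40, templates = NULL,
                               seed = NULL) {
  if (K < 2) stop("K must be at least 2")
  if (mean_dur_ms < 40) stop("mean duration must be at least 40 ms")
  if (snr <= 0) stop("snr must be positive")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n <- round(duration_s * fs)
  if (is.null(templates)) {
    templates <- random_templates(K, montage$positions)
  } else {
    stopifnot(nrow(templates) == K, ncol(templates) == nrow(montage$positions))
  }
  # semi-Markov label sequence
  labels_seq <- integer(n)
  durations <- numeric(0)
  t0 <- 1L
  cur <- sample.int(K, 1)
  min_samp <- round(min_dur_ms * fs / 1000)
  shape <- 4
  while (t0 <= n) {
    dur_ms <- max(min_dur_ms, stats::rgamma(1, shape = shape,
                                            scale = mean_dur_ms / shape))
    len <- max(min_samp, round(dur_ms * fs / 1000))
    t1 <- min(n, t0 + len - 1L)
    labels_seq[t0:t1] <- cur
    durations <- c(durations, (t1 - t0 + 1) / fs * 1000)
    nxt <- sample.int(K - 1, 1)
    cur <- if (nxt >= cur) nxt + 1L else nxt
    t0 <- t1 + 1L
  }
  env <- abs(narrowband_noise(n, c(8, 13), fs))
  env <- env / mean(env)
  signal <- t(templates[labels_seq, , drop = FALSE]) * rep(env, each = nrow(montage$positions))
  noise_sd <- if (is.infinite(snr)) 0 else sqrt(mean(signal^2)) / snr
  data <- signal + matrix(stats::rnorm(length(signal), sd = noise_sd),
                          nrow(signal), ncol(signal))
  rec <- rereference_average(
    eeg_recording(data, fs = fs, labels = montage$labels))
  list(recording = rec,
       truth = list(templates = templates, label_sequence = labels_seq,
                    segment_durations_ms = durations, envelope = env))
}

#' Generate a paired two-condition study with planted effects
#'
#' Emulates a paired pharmacological design: every subject contributes a T0
#' and a T1 recording built by [gen_oscillatory()] from subject-specific band
#' power targets, with a fixed planted effect on theta relative power (T1
#' minus T0) realized in every subject, and band-limited phase coupling on a
#' planted pair subnetwork whose strength drops at T1. Outcome scores are a
#' stated linear function of the subject's T0 coupling strength plus Gaussian
#' noise.
#'
#' @param n_subjects paired subjects (>= 2; default 8).
#' @param theta_effect additive change in the theta relative-power target at
#'   T1 (default -0.07).
#' @param coupling_effect additive change in planted coupling strength at T1
#'   (default -0.3).
#' @param coupling_band band carrying the planted coupling (default "alpha").
#' @param subnetwork character vector of channel labels carrying the planted
#'   coupling (one shared source: all pairs among them form the coupled
#'   clique; default the first 4 channels, a 6-edge subnetwork).
#' @param outcome_intercept,outcome_slope,outcome_sd linear outcome model:
#'   `score = intercept + slope * coupling_T0 + N(0, sd)`.
#' @param duration_s,fs,labels recording parameters (defaults 60 s, 250 Hz,
#'   12 generic channels).
#' @param seed integer seed; fully determines the study.
#' @return List with `recordings` (tibble: subject, condition, recording
#'   list-column), `truth` (per-subject tibble of targets, couplings and
#'   outcome), and `subnetwork` (the coupled clique's edge list).
#' @export
gen_paired_study <- function(n_subjects = 8,
                             theta_effect = -0.07,
                             coupling_effect = -0.3,
                             coupling_band = "alpha",
                             subnetwork = NULL,
                             outcome_intercept = 6, outcome_slope = 10,
                             outcome_sd = 0.5,
                             duration_s = 60, fs = 250,
                             labels = paste0("CH", 1:12), seed = NULL) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  if (is.null(subnetwork)) subnetwork <- labels[seq_len(min(4, length(labels) - 1))]
  pairs <- t(utils::combn(subnetwork, 2))
  base <- c(delta = 0.25, theta = 0.30, alpha = 0.20, beta = 0.15, gamma = 0.10)
  rows <- list(); truth <- list()
  for (s in seq_len(n_subjects)) {
    jit <- stats::runif(5, -0.02, 0.02)
    t0 <- base + jit - mean(jit)
    t1 <- t0
    t1["theta"] <- t1["theta"] + theta_effect
    others <- setdiff(names(t1), "theta")
    t1[others] <- t1[others] - (sum(t1) - 1) * t1[others] / sum(t1[others])
    if (any(t0 < 0 | t0 > 1) || any(t1 < 0 | t1 > 1))
      stop("planted effect drives power targets outside [0, 1]")
    c0 <- stats::runif(1, 0.4, 0.8)
    c1 <- min(1, max(0, c0 + coupling_effect))
    cpl <- function(strength) data.frame(
      chan1 = pairs[, 1], chan2 = pairs[, 2],
      band = coupling_band, strength = strength, source = 1,
      stringsAsFactors = FALSE)
    rec0 <- gen_oscillatory(t0, coupling = cpl(c0), duration_s = duration_s,
                            fs = fs, labels = labels)
    rec1 <- gen_oscillatory(t1, coupling = cpl(c1), duration_s = duration_s,
                            fs = fs, labels = labels)
    outcome <- outcome_intercept + outcome_slope * c0 +
      stats::rnorm(1, sd = outcome_sd)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subject = sprintf("S%02d", s), condition = c("T0", "T1"),
      recording = list(rec0, rec1))
    truth[[length(truth) + 1L]] <- tibble::tibble(
      subject = sprintf("S%02d", s),
      theta_T0 = t0[["theta"]], theta_T1 = t1[["theta"]],
      coupling_T0 = c0, coupling_T1 = c1, outcome = outcome)
  }
  list(recordings = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth),
       subnetwork = pairs)
}
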