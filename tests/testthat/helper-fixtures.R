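# Shared fixtures and independent brute-force oracles. Everything is built in
# code at test time; binary reader fixtures are written to tempdir().

# small montage subset with complete homologous pairing (10 pairs + 3 midline)
test_montage <- function() {
  montage_subset(default_montage(),
                 c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4", "T7", "T8",
                   "P3", "P4", "P7", "P8", "O1", "O2", "FC1", "FC2", "CP1", "CP2",
                   "Fz", "Cz", "Pz"))
}

# --- binary fixtures for the readers ---------------------------------------
write_brainvision_fixture <- function(dir, data, fs, labels,
                                      format = c("float", "int16"),
                                      resolution = 0.1) {
  format <- match.arg(format)
  vhdr <- file.path(dir, "rec.vhdr")
  eegf <- file.path(dir, "rec.eeg")
  fmt <- if (format == "float") "IEEE_FLOAT_32" else "INT_16"
  ch_lines <- vapply(seq_along(labels), function(i)
    sprintf("Ch%d=%s,,%s", i, labels[i],
            if (format == "int16") format(resolution) else "1"), character(1))
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "DataFile=rec.eeg",
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", length(labels)),
    sprintf("SamplingInterval=%g", 1e6 / fs),
    "[Binary Infos]",
    sprintf("BinaryFormat=%s", fmt),
    "[Channel Infos]",
    ch_lines), vhdr)
  con <- file(eegf, "wb")
  if (format == "float") {
    writeBin(as.numeric(as.vector(data)), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(round(as.vector(data) / resolution)), con, size = 2L,
             endian = "little")
  }
  close(con)
  vhdr
}

write_edf_fixture <- function(path, data, fs, labels, record_dur = 1) {
  # int16 EDF with physical range [-500, 500] uV
  ns <- nrow(data)
  n_per_rec <- as.integer(fs * record_dur)
  n_records <- ncol(data) %/% n_per_rec
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  hdr <- paste0(pad("0", 8), pad("patient", 80), pad("rec", 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(256 * (ns + 1), 8), pad("", 44), pad(n_records, 8),
                pad(record_dur, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(c(16, labels), c(80, rep("", ns)), c(8, rep("uV", ns)),
                 c(8, rep("-500", ns)), c(8, rep("500", ns)),
                 c(8, rep("-32768", ns)), c(8, rep("32767", ns)),
                 c(80, rep("", ns)), c(8, rep(n_per_rec, ns)),
                 c(32, rep("", ns)))
  for (f in fields) {
    w <- as.integer(f[1])
    for (v in f[-1]) writeChar(pad(v, w), con, eos = NULL)
  }
  gain <- 1000 / 65535
  for (r in seq_len(n_records)) {
    for (ci in seq_len(ns)) {
      x <- data[ci, ((r - 1) * n_per_rec + 1):(r * n_per_rec)]
      writeBin(as.integer(round(x / gain)), con, size = 2L, endian = "little")
    }
  }
  close(con)
  path
}

# --- independent oracles ----------------------------------------------------
plv_oracle <- function(phases) {
  # phases: M x C x N; four-level nested loops, straight from the formula
  M <- dim(phases)[1]; C <- dim(phases)[2]; N <- dim(phases)[3]
  out <- matrix(0, C, C)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    acc <- 0
    for (m in seq_len(M)) {
      s <- 0 + 0i
      for (n in seq_len(N)) {
        s <- s + exp(-1i * (phases[m, j, n] - phases[m, i, n]))
      }
      acc <- acc + Mod(s) / N
    }
    out[i, j] <- acc / M
  }
  diag(out) <- 1
  out
}

relative_power_oracle <- function(psd, scheme) {
  # per-channel per-band fractions by explicit per-bin summation
  tot <- attr(scheme, "total_range")
  out <- matrix(0, length(psd$labels), nrow(scheme))
  for (ch in seq_along(psd$labels)) {
    denom <- 0
    for (f in seq_along(psd$freqs)) {
      if (psd$freqs[f] >= tot[1] - 1e-9 && psd$freqs[f] <= tot[2] + 1e-9)
        denom <- denom + psd$psd[ch, f]
    }
    for (b in seq_len(nrow(scheme))) {
      s <- 0
      for (f in seq_along(psd$freqs)) {
        if (psd$freqs[f] >= scheme$low[b] - 1e-9 &&
            psd$freqs[f] <= scheme$high[b] + 1e-9)
          s <- s + psd$psd[ch, f]
      }
      out[ch, b] <- s / denom
    }
  }
  dimnames(out) <- list(psd$labels, scheme$band)
  out
}

bsi_oracle <- function(psd, montage, scheme) {
  pairs <- montage$homologous_pairs
  pairs <- pairs[pairs$left %in% psd$labels & pairs$right %in% psd$labels, ]
  out <- data.frame(band = scheme$band, pdBSI = NA_real_, rBSI = NA_real_)
  for (b in seq_len(nrow(scheme))) {
    bins <- which(psd$freqs >= scheme$low[b] - 1e-9 &
                  psd$freqs <= scheme$high[b] + 1e-9)
    vals <- c()
    for (p in seq_len(nrow(pairs))) {
      l <- psd$psd[match(pairs$left[p], psd$labels), bins]
      r <- psd$psd[match(pairs$right[p], psd$labels), bins]
      for (k in seq_along(bins)) {
        if (r[k] + l[k] > 0) vals <- c(vals, abs(r[k] - l[k]) / (r[k] + l[k]))
      }
    }
    out$pdBSI[b] <- mean(vals)
    lbar <- colMeans(psd$psd[match(pairs$left, psd$labels), bins, drop = FALSE])
    rbar <- colMeans(psd$psd[match(pairs$right, psd$labels), bins, drop = FALSE])
    keep <- (lbar + rbar) > 0
    out$rBSI[b] <- mean(abs(rbar[keep] - lbar[keep]) / (rbar[keep] + lbar[keep]))
  }
  out
}

# segment-walking oracle for the per-class microstate features
microstate_features_oracle <- function(seq, gfp_values, templates, rec) {
  K <- seq$K
  fs <- seq$fs
  segs <- as.data.frame(seq$segments)
  open <- segs[!segs$truncated, ]
  labeled <- which(!is.na(seq$labels))
  total_s <- length(labeled) / fs
  corr_map <- function(t, k) {
    stats::cor(rec$data[, t], templates$maps[k, ])
  }
  res <- data.frame(class = seq$class_names, gev = NA_real_, dur = NA_real_,
                    occ = NA_real_, cov = NA_real_, interval = NA_real_,
                    mgfp = NA_real_)
  denom <- sum(gfp_values[labeled]^2)
  for (k in seq_len(K)) {
    sk <- open[open$class == k, ]
    samp <- labeled[seq$labels[labeled] == k]
    if (nrow(sk)) {
      res$dur[k] <- mean((sk$end - sk$start) / fs * 1000)
      res$occ[k] <- nrow(sk) / total_s
    }
    if (length(samp)) {
      res$cov[k] <- length(samp) / length(labeled)
      res$mgfp[k] <- mean(gfp_values[samp])
      g <- 0
      for (t in samp) g <- g + (gfp_values[t] * corr_map(t, k))^2
      res$gev[k] <- g / denom
    }
    ivals <- c()
    for (cs in rec$segments) {
      inseg <- sk[sk$start >= cs[1] & sk$end <= cs[2], ]
      if (nrow(inseg) >= 2) {
        for (i in seq_len(nrow(inseg) - 1)) {
          ivals <- c(ivals, (inseg$start[i + 1] - inseg$end[i]) / fs * 1000)
        }
      }
    }
    if (length(ivals)) res$interval[k] <- mean(ivals)
  }
  res
}

# build a microstate_sequence by hand from a label vector (single segment)
sequence_from_labels <- function(labels_vec, fs, K, class_names = as.character(seq_len(K))) {
  rec_segments <- list(c(0L, length(labels_vec)))
  r <- rle(labels_vec)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- tibble::tibble(start = starts - 1L, end = ends, class = r$values,
                         truncated = seq_along(r$lengths) %in% c(1L, length(r$lengths)))
  structure(list(labels = labels_vec, segments = segs, fs = fs, K = K,
                 class_names = class_names),
            class = "microstate_sequence")
}

# simple phase unwrap for test assertions
pracma_unwrap <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}
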