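#' Global field power
#'
#' The population (divide-by-C) standard deviation of the scalp potential
#' across channels at each sample. For a two-channel sample `c(1, -1)` the GFP
#' is exactly 1.
#'
#' @param rec a common-average-referenced [eeg_recording()].
#' @return Numeric vector, one nonnegative value per sample.
#' @export
gfp <- function(rec) {
  mu <- colMeans(rec$data)
  sqrt(colMeans(sweep(rec$data, 2L, mu)^2))
}

# Pearson spatial correlation between map columns: X (C x n), T (C x K)
# -> n x K matrix of correlations across channels
spatial_corr_matrix <- function(X, Tm) {
  Xc <- sweep(X, 2L, colMeans(X))
  Tc <- sweep(Tm, 2L, colMeans(Tm))
  Xn <- sweep(Xc, 2L, sqrt(colSums(Xc^2)), `/`)
  Tn <- sweep(Tc, 2L, sqrt(colSums(Tc^2)), `/`)
  crossprod(Xn, Tn)
}

#' Select GFP-peak maps for clustering
#'
#' Local GFP maxima are located within continuity segments; peaks in the
#' lowest 15% of peak GFP values are discarded (rank-based, stable under
#' ties), as are peaks whose GFP exceeds the mean by more than three standard
#' deviations of the peak GFP values. The surviving samples' maps ("original
#' maps") feed the modified k-means.
#'
#' @param gfp_values per-sample GFP from [gfp()].
#' @param rec the matching [eeg_recording()].
#' @param low_discard fraction of lowest peaks discarded (default 0.15).
#' @param high_sd SD multiplier for the upper discard rule (default 3).
#' @return List with `maps` (surviving peaks x channels) and `peaks`
#'   (1-based sample indices).
#' @export
select_peak_maps <- function(gfp_values, rec, low_discard = 0.15, high_sd = 3) {
  peaks <- integer(0)
  for (s in rec$segments) {
    idx <- seg_idx(s)
    g <- gfp_values[idx]
    if (length(g) < 3) next
    loc <- which(g[-c(1, length(g))] > g[-c(length(g) - 1, length(g))] &
                 g[-c(1, length(g))] > g[-c(1, 2)]) + 1L
    peaks <- c(peaks, idx[loc])
  }
  if (length(peaks) < 10) stop("fewer than 10 GFP local maxima")
  pv <- gfp_values[peaks]
  n_low <- floor(low_discard * length(peaks))
  drop_low <- if (n_low > 0) order(pv)[seq_len(n_low)] else integer(0)
  thr <- mean(pv) + high_sd * stats::sd(pv)
  drop_high <- which(pv > thr)
  keep <- setdiff(seq_along(peaks), union(drop_low, drop_high))
  if (!length(keep)) stop("all GFP peaks discarded")
  peaks <- peaks[keep]
  list(maps = t(rec$data[, peaks, drop = FALSE]), peaks = peaks)
}

#' Polarity-invariant modified k-means
#'
#' Clusters topographic maps ignoring polarity: each map is assigned to the
#' template maximizing the squared spatial correlation, and each template is
#' updated to the dominant eigenvector of the cross-product matrix of its
#' assigned maps. Iteration stops when the relative change in global explained
#' variance (GEV) falls below `tol`; the best of `restarts` random restarts
#' (by GEV) is returned. An emptied cluster is re-seeded from the worst-fit
#' map.
#'
#' @param maps numeric matrix, maps x channels (e.g., GFP-peak maps).
#' @param K number of clusters (default 4).
#' @param restarts random restarts (default 10).
#' @param seed integer seed for reproducible restarts.
#' @param max_iter,tol iteration controls.
#' @return A `microstate_templates` object: `maps` (K x channels, unit-norm
#'   rows), `labels`, plus `assignment` and `gev` for the input maps.
#' @export
modified_kmeans <- function(maps, K = 4, restarts = 10, seed = NULL,
                            max_iter = 100, tol = 1e-6) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < K) stop("need at least K maps")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  g <- apply(maps, 1L, function(m) sqrt(mean((m - mean(m))^2)))
  denom <- sum(g^2)
  best <- NULL
  for (r in seq_len(restarts)) {
    Tm <- maps[sample.int(n, K), , drop = FALSE]
    Tm <- Tm / sqrt(rowSums(Tm^2))
    gev_prev <- -Inf
    for (it in seq_len(max_iter)) {
      cors <- spatial_corr_matrix(t(maps), t(Tm))      # n x K
      assign_k <- max.col(cors^2, ties.method = "first")
      for (k in seq_len(K)) {
        sel <- which(assign_k == k)
        if (!length(sel)) {
          fit <- cors[cbind(seq_len(n), assign_k)]^2
          worst <- which.min(fit)
          assign_k[worst] <- k
          sel <- worst
        }
        Xk <- maps[sel, , drop = FALSE]
        S <- crossprod(Xk)
        v <- eigen(S, symmetric = TRUE)$vectors[, 1]
        Tm[k, ] <- v / sqrt(sum(v^2))
      }
      cors <- spatial_corr_matrix(t(maps), t(Tm))
      assign_k <- max.col(cors^2, ties.method = "first")
      gev <- sum((g * cors[cbind(seq_len(n), assign_k)])^2) / denom
      if (is.finite(gev_prev) && abs(gev - gev_prev) < tol * max(gev, 1e-12)) break
      gev_prev <- gev
    }
    if (is.null(best) || gev > best$gev) {
      best <- list(Tm = Tm, assignment = assign_k, gev = gev)
    }
  }
  structure(list(maps = best$Tm, labels = as.character(seq_len(K)),
                 assignment = best$assignment, gev = best$gev,
                 channel_labels = colnames(maps)),
            class = "microstate_templates")
}

#' @export
print.microstate_templates <- function(x, ...) {
  cat(sprintf("<microstate_templates> K = %d (%s), %d channels, GEV %.3f\n",
              nrow(x$maps), paste(x$labels, collapse = ", "), ncol(x$maps),
              x$gev %||% NA_real_))
  invisible(x)
}

#' Parametric canonical microstate reference maps
#'
#' Synthetic reconstructions of the four normative resting-state topographies
#' used only to give group templates consistent A-D names: A and B are the two
#' diagonal left/right gradients, C the anterior-posterior gradient, D the
#' fronto-central (radial) pattern. They are computed from the montage
#' geometry, not measured data, and serve as labeling anchors, not as
#' templates.
#'
#' @param montage an [eeg_montage()].
#' @return Matrix channels x 4 with columns A-D, unit-norm, average-referenced.
#' @export
canonical_maps <- function(montage) {
  p <- montage$positions
  maps <- cbind(A = p[, 1] + p[, 2],
                B = -p[, 1] + p[, 2],
                C = p[, 2],
                D = p[, 3] - 0.5 * p[, 2]^2)
  maps <- sweep(maps, 2L, colMeans(maps))
  sweep(maps, 2L, sqrt(colSums(maps^2)), `/`)
}

# best one-to-one assignment of K templates to K references, maximizing the
# total |spatial correlation| (exhaustive over permutations; K is small)
assign_canonical <- function(templates, refs) {
  K <- nrow(templates)
  cors <- abs(spatial_corr_matrix(t(templates), refs))
  perms <- permutations_of(K)
  scores <- vapply(perms, function(p) sum(cors[cbind(seq_len(K), p)]), numeric(1))
  perms[[which.max(scores)]]
}

permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  sub <- permutations_of(K - 1)
  out <- list()
  for (p in sub) for (i in seq_len(K)) {
    out[[length(out) + 1L]] <- append(p, K, after = i - 1L)
  }
  out
}

#' Group-level microstate templates
#'
#' Pools the per-recording templates and runs a second modified k-means over
#' them; the resulting group templates are then named A-D by maximal absolute
#' spatial correlation to the canonical reference maps under a one-to-one
#' assignment (exhaustive over the K! pairings). Without a montage the
#' clusters keep numeric names.
#'
#' @param per_recording list (length >= 2) of `microstate_templates`.
#' @param K number of group clusters (defaults to the K of the inputs).
#' @param seed integer seed.
#' @param montage optional [eeg_montage()] for canonical A-D naming.
#' @param ... passed to [modified_kmeans()].
#' @return A `microstate_templates` object with labels A-D (or numeric).
#' @export
group_templates <- function(per_recording, K = NULL, seed = NULL,
                            montage = NULL, ...) {
  if (length(per_recording) < 2) stop("need templates from at least 2 recordings")
  pooled <- do.call(rbind, lapply(per_recording, function(t) t$maps))
  if (is.null(K)) K <- nrow(per_recording[[1]]$maps)
  res <- modified_kmeans(pooled, K = K, seed = seed, ...)
  res$channel_labels <- per_recording[[1]]$channel_labels
  if (!is.null(montage) && !is.null(res$channel_labels) &&
      all(res$channel_labels %in% montage$labels) && K == 4) {
    refs <- canonical_maps(montage)[res$channel_labels, , drop = FALSE]
    perm <- assign_canonical(res$maps, refs)
    res$labels <- colnames(refs)[perm]
    ord <- order(res$labels)
    res$maps <- res$maps[ord, , drop = FALSE]
    res$labels <- res$labels[ord]
    res$assignment <- NULL   # assignment indices no longer meaningful
  }
  res
}

#' Back-fit templates and smooth the label sequence
#'
#' Every in-segment sample is labeled by the template with the largest
#' absolute spatial correlation to its map. Temporal smoothing then repeatedly
#' reassigns the shortest non-truncated segment shorter than `min_dur_ms`
#' (ceiling in samples): each of its samples moves to whichever neighboring
#' segment's class correlates better (in absolute value) with that sample's
#' map, until no short non-truncated segment remains. The first and last
#' segments of each continuity segment are flagged as (potentially) truncated.
#'
#' @param rec a common-average-referenced [eeg_recording()].
#' @param templates a `microstate_templates`.
#' @param min_dur_ms minimum segment duration in ms (default 30).
#' @return A `microstate_sequence`: per-sample `labels` (class index, NA
#'   outside continuity segments), `segments` tibble (`start`, `end` 0-based
#'   half-open samples, `class`, `truncated`), `fs`, `K`, `class_names`.
#' @export
backfit_smooth <- function(rec, templates, min_dur_ms = 30) {
  K <- nrow(templates$maps)
  min_samp <- ceiling(min_dur_ms * rec$fs / 1000)
  labels <- rep(NA_integer_, n_samples(rec))
  cors_all <- abs(spatial_corr_matrix(rec$data, t(templates$maps)))  # samples x K
  for (s in rec$segments) {
    idx <- seg_idx(s)
    lab <- max.col(cors_all[idx, , drop = FALSE], ties.method = "first")
    lab <- smooth_labels(lab, cors_all[idx, , drop = FALSE], min_samp)
    labels[idx] <- lab
  }
  segments <- label_runs(labels, rec$segments)
  structure(list(labels = labels, segments = segments, fs = rec$fs, K = K,
                 class_names = templates$labels),
            class = "microstate_sequence")
}

# iterative short-segment rejection within one continuity segment
smooth_labels <- function(lab, cors, min_samp) {
  repeat {
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    n_runs <- length(r$lengths)
    interior <- seq_len(n_runs)[-c(1L, n_runs)]
    if (!length(interior)) break
    short <- interior[r$lengths[interior] < min_samp]
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    prev_class <- r$values[i - 1L]
    next_class <- r$values[i + 1L]
    for (t in starts[i]:ends[i]) {
      lab[t] <- if (cors[t, prev_class] >= cors[t, next_class]) prev_class else next_class
    }
  }
  lab
}

label_runs <- function(labels, segs) {
  out <- list()
  for (s in segs) {
    idx <- seg_idx(s)
    r <- rle(labels[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    n_runs <- length(r$lengths)
    out[[length(out) + 1L]] <- tibble::tibble(
      start = s[1] + starts - 1L,
      end = s[1] + ends,
      class = r$values,
      truncated = seq_len(n_runs) %in% c(1L, n_runs))
  }
  dplyr::bind_rows(out)
}

#' Microstate feature families
#'
#' Computes, per class X: GEV (GFP-weighted explained topographic variance
#' over all labeled samples), mean segment duration (ms), occurrence (non-
#' truncated segments per second of analyzed time), coverage (fraction of
#' labeled samples), mean interval (ms; the average gap between the end of one
#' X segment and the start of the next, within a continuity segment), mean GFP
#' over X samples, and the K x K matrices SC (mean |spatial correlation| of
#' template X with the maps labeled Y) and TP (transition probabilities
#' between consecutive non-truncated segments). Truncated segments are
#' excluded from all segment-based features; an absent class yields NA, not
#' zero.
#'
#' @param seq a [backfit_smooth()] sequence.
#' @param gfp_values per-sample GFP of the same recording.
#' @param templates the `microstate_templates` used for back-fitting.
#' @param rec the recording itself.
#' @return A `microstate_features` object: tibble `per_class` plus matrices
#'   `sc` and `tp`.
#' @export
microstate_features <- function(seq, gfp_values, templates, rec) {
  K <- seq$K
  cls_names <- seq$class_names
  fs <- seq$fs
  labeled <- !is.na(seq$labels)
  total_time_s <- sum(labeled) / fs
  denom_gev <- sum(gfp_values[labeled]^2)
  cors <- spatial_corr_matrix(rec$data, t(templates$maps))   # samples x K
  segs <- seq$segments
  open_segs <- segs[!segs$truncated, , drop = FALSE]

  per_class <- lapply(seq_len(K), function(k) {
    samp <- which(labeled & seq$labels == k)
    segs_k <- open_segs[open_segs$class == k, , drop = FALSE]
    dur <- (segs_k$end - segs_k$start) / fs * 1000
    # intervals between consecutive X segments within a continuity segment
    ivals <- numeric(0)
    for (s in rec$segments) {
      in_seg <- segs_k[segs_k$start >= s[1] & segs_k$end <= s[2], , drop = FALSE]
      if (nrow(in_seg) >= 2) {
        ivals <- c(ivals, (in_seg$start[-1] - in_seg$end[-nrow(in_seg)]) / fs * 1000)
      }
    }
    tibble::tibble(
      class = cls_names[k],
      gev = if (length(samp)) sum((gfp_values[samp] * cors[samp, k])^2) / denom_gev
            else NA_real_,
      mean_duration_ms = if (nrow(segs_k)) mean(dur) else NA_real_,
      occurrence = if (nrow(segs_k)) nrow(segs_k) / total_time_s else NA_real_,
      coverage = if (length(samp)) length(samp) / sum(labeled) else NA_real_,
      mean_interval_ms = if (length(ivals)) mean(ivals) else NA_real_,
      mean_gfp = if (length(samp)) mean(gfp_values[samp]) else NA_real_)
  })

  sc <- matrix(NA_real_, K, K, dimnames = list(cls_names, cls_names))
  for (y in seq_len(K)) {
    samp_y <- which(labeled & seq$labels == y)
    if (length(samp_y)) sc[, y] <- colMeans(abs(cors[samp_y, , drop = FALSE]))
  }

  tp <- matrix(0, K, K, dimnames = list(cls_names, cls_names))
  for (s in rec$segments) {
    in_seg <- segs[segs$start >= s[1] & segs$end <= s[2], , drop = FALSE]
    keep <- !in_seg$truncated
    cls <- in_seg$class
    for (i in seq_len(nrow(in_seg) - 1)) {
      if (keep[i] && keep[i + 1]) tp[cls[i], cls[i + 1]] <- tp[cls[i], cls[i + 1]] + 1
    }
  }
  row_tot <- rowSums(tp)
  tp <- tp / ifelse(row_tot > 0, row_tot, NA_real_)

  structure(list(per_class = dplyr::bind_rows(per_class), sc = sc, tp = tp),
            class = "microstate_features")
}

#' @export
print.microstate_features <- function(x, ...) {
  cat("<microstate_features>\n")
  print(x$per_class)
  invisible(x)
}

#' Per-recording microstate templates from GFP peaks
#'
#' Convenience pipeline: [gfp()] -> [select_peak_maps()] -> [modified_kmeans()].
#' @param rec a common-average-referenced [eeg_recording()].
#' @param K clusters (default 4).
#' @param seed integer seed.
#' @param ... passed to [modified_kmeans()].
#' @export
recording_templates <- function(rec, K = 4, seed = NULL, ...) {
  g <- gfp(rec)
  pk <- select_peak_maps(g, rec)
  res <- modified_kmeans(pk$maps, K = K, seed = seed, ...)
  res$channel_labels <- rec$labels
  res
}

#' Full microstate analysis of one recording against given templates
#'
#' Back-fits, smooths, and computes all feature families.
#' @inheritParams backfit_smooth
#' @param min_dur_ms minimum segment duration (ms).
#' @return A `microstate_features` object (the sequence is attached as
#'   attribute `"sequence"`).
#' @export
microstate_analysis <- function(rec, templates, min_dur_ms = 30) {
  sq <- backfit_smooth(rec, templates, min_dur_ms = min_dur_ms)
  g <- gfp(rec)
  feats <- microstate_features(sq, g, templates, rec)
  attr(feats, "sequence") <- sq
  feats
}
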