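test_that("GFP is the population SD across channels", {
  rec <- eeg_recording(matrix(c(1, -1, 0, 0, 3, -3), 2), 250)
  expect_equal(gfp(rec), c(1, 0, 3))
  # homogeneity: scaling the data scales GFP by |c|
  rec2 <- rec; rec2$data <- rec2$data * -2.5
  expect_equal(gfp(rec2), 2.5 * gfp(rec))
})

test_that("GFP peak selection applies the lowest-15% and mean+3SD rules", {
  fs <- 250
  # 100 equal-height peaks: triangular waves, no peak above mean + 3 SD
  n_peaks <- 100
  g_wave <- rep(c(0, 1), n_peaks + 1)
  base <- matrix(0, 2, length(g_wave))
  base[1, ] <- g_wave; base[2, ] <- -g_wave
  rec <- eeg_recording(base, fs)
  pk <- select_peak_maps(gfp(rec), rec)
  expect_equal(length(pk$peaks), n_peaks - 15)

  # one extreme outlier peak gets removed by the 3-SD rule
  heights <- c(rep(1, 99), 10) * (1 + 0.01 * seq_len(100))  # break ties
  g2 <- rep(0, 201); g2[seq(2, 200, by = 2)] <- heights
  rec2 <- eeg_recording(rbind(g2, -g2), fs)
  pk2 <- select_peak_maps(gfp(rec2), rec2)
  outlier_sample <- which(g2 == max(heights))
  expect_false(outlier_sample %in% pk2$peaks)

  # a monotone ramp has no interior maxima
  ramp <- eeg_recording(rbind(seq_len(100), -seq_len(100)), fs)
  expect_error(select_peak_maps(gfp(ramp), ramp), "maxima")
})

test_that("modified k-means recovers exact templates and ignores polarity", {
  set.seed(18)
  C <- 12
  Tm <- qr.Q(qr(matrix(rnorm(C * 4), C)))[, 1:4]    # orthogonal maps
  Tm <- sweep(Tm, 2L, colMeans(Tm))                  # average-referenced
  Tm <- sweep(Tm, 2L, sqrt(colSums(Tm^2)), `/`)
  signs <- sample(c(-1, 1), 200, replace = TRUE)
  scales <- runif(200, 0.5, 2)
  cls <- sample(1:4, 200, replace = TRUE)
  maps <- t(Tm[, cls]) * signs * scales
  fit <- modified_kmeans(maps, K = 4, restarts = 5, seed = 1)
  cors <- abs(spatial_corr_matrix(Tm, t(fit$maps)))
  expect_equal(sort(apply(cors, 1, max)), rep(1, 4), tolerance = 1e-9)
  expect_equal(fit$gev, 1, tolerance = 1e-9)
  # flipping every map's sign changes nothing
  fit2 <- modified_kmeans(-maps, K = 4, restarts = 5, seed = 1)
  expect_equal(abs(fit2$maps), abs(fit$maps), tolerance = 1e-9)
  expect_equal(fit2$assignment, fit$assignment)
  expect_error(modified_kmeans(maps[1:3, ], K = 4), "at least")
})

test_that("group templates pool recordings and take canonical A-D names", {
  m <- test_montage()
  refs <- canonical_maps(m)
  set.seed(19)
  noisy <- function() {
    t1 <- t(refs) + matrix(rnorm(4 * nrow(refs), sd = 0.02), 4)
    t1 <- t1 / sqrt(rowSums(t1^2))
    structure(list(maps = t1, labels = as.character(1:4),
                   channel_labels = m$labels),
              class = "microstate_templates")
  }
  grp <- group_templates(list(noisy(), noisy(), noisy()), seed = 2, montage = m)
  expect_equal(grp$labels, c("A", "B", "C", "D"))
  cors <- abs(spatial_corr_matrix(refs, t(grp$maps)))
  expect_true(all(diag(cors) > 0.99))
  # degenerate pooling: identical inputs reproduce themselves up to sign
  same <- noisy()
  grp2 <- group_templates(list(same, same), seed = 3)
  cors2 <- abs(spatial_corr_matrix(t(same$maps), t(grp2$maps)))
  expect_true(all(apply(cors2, 1, max) > 0.999))
  expect_error(group_templates(list(same)), "at least 2")
})

test_that("back-fitting recovers noiseless boundaries and smooths short runs", {
  m <- test_montage()
  g <- gen_microstate_eeg(K = 4, mean_dur_ms = 100, snr = Inf,
                          duration_s = 10, fs = 250, montage = m, seed = 20)
  tpl <- structure(list(maps = g$truth$templates,
                        labels = as.character(1:4),
                        channel_labels = m$labels),
                   class = "microstate_templates")
  sq <- backfit_smooth(g$recording, tpl)
  # noiseless: recovered labels equal the generating sequence up to class ids
  agree <- mean(sq$labels == g$truth$label_sequence)
  expect_gt(agree, 0.999)
  # the smoothing floor: ceil(30 ms * 250 / 1000) = 8 samples
  segs <- sq$segments
  open <- segs[!segs$truncated, ]
  expect_true(all(open$end - open$start >= 8))

  # a one-sample spurious run between two long runs of the same class is absorbed
  labs <- c(rep(1L, 50), 2L, rep(1L, 50))
  cors <- matrix(0.5, 101, 2); cors[51, 2] <- 0.9
  sm <- zolpiscope:::smooth_labels(labs, cors, 8)
  expect_equal(sm, rep(1L, 101))
})

test_that("microstate features follow their printed definitions", {
  fs <- 250
  # class-1 segments at 0-96, 200-296, 400-496 ms; class 2 fills the gaps
  ms <- function(a) as.integer(round(a * fs / 1000))
  labs <- rep(2L, ms(600))
  labs[(ms(0) + 1):ms(96)] <- 1L
  labs[(ms(200) + 1):ms(296)] <- 1L
  labs[(ms(400) + 1):ms(496)] <- 1L
  sq <- sequence_from_labels(labs, fs, K = 2)
  # interval terms: (200 - 96) and (400 - 296) -> mean 104 ms
  rec <- eeg_recording(matrix(rnorm(2 * length(labs)), 2), fs)
  tpl <- structure(list(maps = matrix(c(1, -1, -1, 1), 2, byrow = TRUE),
                        labels = c("1", "2")), class = "microstate_templates")
  ft <- microstate_features(sq, gfp(rec), tpl, rec)
  expect_equal(ft$per_class$mean_interval_ms[1], 104)

  # occurrence: 5 non-truncated class-1 segments in 10 s -> 0.5 / s
  labs2 <- rep(2L, 10 * fs)
  starts <- seq(200, by = 450, length.out = 5)
  for (st in starts) labs2[st:(st + 25)] <- 1L
  sq2 <- sequence_from_labels(labs2, fs, K = 2)
  rec2 <- eeg_recording(matrix(rnorm(2 * length(labs2)), 2), fs)
  ft2 <- microstate_features(sq2, gfp(rec2), tpl, rec2)
  expect_equal(ft2$per_class$occurrence[1], 0.5)

  # all maps exactly equal to template X: SC_XX = 1, GEV_X = 1
  map <- c(1, -1)
  rec3 <- eeg_recording(matrix(rep(map * rep(runif(100, 0.5, 2), each = 2)), 2),
                        fs)
  labs3 <- rep(1L, 100)
  sq3 <- sequence_from_labels(labs3, fs, K = 2)
  ft3 <- microstate_features(sq3, gfp(rec3), tpl, rec3)
  expect_equal(ft3$sc["1", "1"], 1)
  expect_equal(ft3$per_class$gev[1], 1)
  expect_true(is.na(ft3$per_class$gev[2]))   # absent class reported missing
})

test_that("random sequences match the segment-walking oracle and TP rows sum to 1", {
  set.seed(21)
  m <- test_montage()
  g <- gen_microstate_eeg(K = 4, mean_dur_ms = 80, snr = 4, duration_s = 12,
                          fs = 250, montage = m, seed = 22)
  tpl <- structure(list(maps = g$truth$templates, labels = as.character(1:4),
                        channel_labels = m$labels),
                   class = "microstate_templates")
  sq <- backfit_smooth(g$recording, tpl)
  gv <- gfp(g$recording)
  ft <- microstate_features(sq, gv, tpl, g$recording)
  oracle <- microstate_features_oracle(sq, gv, tpl, g$recording)
  expect_equal(ft$per_class$gev, oracle$gev, tolerance = 1e-9)
  expect_equal(ft$per_class$mean_duration_ms, oracle$dur, tolerance = 1e-9)
  expect_equal(ft$per_class$occurrence, oracle$occ, tolerance = 1e-9)
  expect_equal(ft$per_class$coverage, oracle$cov, tolerance = 1e-9)
  expect_equal(ft$per_class$mean_interval_ms, oracle$interval, tolerance = 1e-9)
  expect_equal(ft$per_class$mean_gfp, oracle$mgfp, tolerance = 1e-9)
  present <- rowSums(ft$tp, na.rm = TRUE) > 0
  expect_equal(rowSums(ft$tp)[present], rep(1, sum(present)),
               ignore_attr = TRUE)
  expect_equal(sum(ft$per_class$coverage), 1)
  expect_true(all(ft$sc >= 0 & ft$sc <= 1, na.rm = TRUE))
})

test_that("flipping the recording's sign changes no microstate feature", {
  m <- test_montage()
  g <- gen_microstate_eeg(K = 4, mean_dur_ms = 90, snr = 5, duration_s = 10,
                          fs = 250, montage = m, seed = 23)
  tpl <- recording_templates(g$recording, K = 4, seed = 4)
  f1 <- microstate_analysis(g$recording, tpl)
  flipped <- g$recording; flipped$data <- -flipped$data
  f2 <- microstate_analysis(flipped, tpl)
  expect_equal(f1$per_class, f2$per_class, tolerance = 1e-9)
  expect_equal(f1$sc, f2$sc, tolerance = 1e-9)
  expect_equal(f1$tp, f2$tp, tolerance = 1e-9)
})

test_that("two-level clustering recovers templates and dynamics at snr 5", {
  m <- test_montage()
  n_seeds <- 4
  runs <- lapply(seq_len(n_seeds), function(s)
    gen_microstate_eeg(K = 4, mean_dur_ms = 100, snr = 5, duration_s = 25,
                       fs = 250, montage = m, seed = 300 + s))
  per <- lapply(seq_along(runs), function(i)
    recording_templates(runs[[i]]$recording, K = 4, seed = 40 + i))
  for (i in seq_along(runs)) {
    cors <- abs(spatial_corr_matrix(t(runs[[i]]$truth$templates),
                                    t(per[[i]]$maps)))
    expect_true(all(apply(cors, 1, max) > 0.95))
  }
  # duration / occurrence recovery within 15%
  rel_err <- sapply(seq_along(runs), function(i) {
    ft <- microstate_analysis(runs[[i]]$recording, per[[i]])
    truth_dur <- mean(runs[[i]]$truth$segment_durations_ms)
    est_dur <- mean(ft$per_class$mean_duration_ms, na.rm = TRUE)
    abs(est_dur - truth_dur) / truth_dur
  })
  expect_true(all(rel_err < 0.15))
})
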