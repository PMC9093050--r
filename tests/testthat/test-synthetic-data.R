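test_that("a fixed seed fully determines every generator's output", {
  tg <- c(delta = 0.2, theta = 0.2, alpha = 0.2, beta = 0.2, gamma = 0.2)
  a <- gen_oscillatory(tg, duration_s = 10, labels = paste0("CH", 1:3), seed = 50)
  b <- gen_oscillatory(tg, duration_s = 10, labels = paste0("CH", 1:3), seed = 50)
  expect_identical(a$data, b$data)
  m <- test_montage()
  g1 <- gen_microstate_eeg(duration_s = 5, montage = m, seed = 51)
  g2 <- gen_microstate_eeg(duration_s = 5, montage = m, seed = 51)
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(g1$truth$label_sequence, g2$truth$label_sequence)
  s1 <- gen_paired_study(n_subjects = 2, duration_s = 6,
                         labels = paste0("CH", 1:8), seed = 52)
  s2 <- gen_paired_study(n_subjects = 2, duration_s = 6,
                         labels = paste0("CH", 1:8), seed = 52)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$recordings$recording[[1]]$data,
                   s2$recordings$recording[[1]]$data)
  # generators restore the caller's RNG state
  set.seed(99); before <- .Random.seed
  invisible(gen_oscillatory(tg, duration_s = 5, labels = "CH1",
                            rereference = FALSE, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("uniform band targets are realized within +/- 0.05", {
  tg <- c(delta = 0.2, theta = 0.2, alpha = 0.2, beta = 0.2, gamma = 0.2)
  rec <- gen_oscillatory(tg, duration_s = 60, labels = paste0("CH", 1:3),
                         seed = 53)
  rp <- relative_power(welch_psd(rec), spectral_bands())
  five <- dplyr::filter(rp$channel, .data$band %in% primary_bands())
  expect_true(all(abs(five$relative_power - 0.2) < 0.05))
})

test_that("generator preconditions are enforced", {
  bad <- c(delta = 0.5, theta = 0.2, alpha = 0.2, beta = 0.2, gamma = 0.2)
  expect_error(gen_oscillatory(bad, duration_s = 10), "sum to 1")
  tg <- c(delta = 0.2, theta = 0.2, alpha = 0.2, beta = 0.2, gamma = 0.2)
  expect_error(gen_oscillatory(tg, duration_s = 1), "3 cycles")
  cpl <- data.frame(chan1 = "CH1", chan2 = "CH2", band = "alpha", strength = 2)
  expect_error(gen_oscillatory(tg, coupling = cpl, duration_s = 10), "\\[0, 1\\]")
  expect_error(gen_microstate_eeg(K = 1), "at least 2")
  expect_error(gen_microstate_eeg(snr = 0), "positive")
  expect_error(gen_microstate_eeg(mean_dur_ms = 20), "40 ms")
  expect_error(gen_paired_study(n_subjects = 1), "at least 2")
  expect_error(gen_paired_study(n_subjects = 2, theta_effect = -0.5,
                                duration_s = 6, seed = 1),
               "outside")
})

test_that("full coupling gives near-unit PLV on the planted pair", {
  cpl <- data.frame(chan1 = "CH1", chan2 = "CH2", band = "alpha",
                    strength = 1.0)
  rec <- gen_oscillatory(c(delta = 0, theta = 0, alpha = 1, beta = 0,
                           gamma = 0),
                         coupling = cpl, duration_s = 40,
                         labels = paste0("CH", 1:12), seed = 54)
  rec$reference <- "laplacian"
  cm <- band_plv(rec, "alpha")
  expect_gt(cm$values["CH1", "CH2"], 0.95)
  # and an uncoupled pair sits near the narrowband null level of the
  # estimator (about 0.28 for a 5 Hz-wide band and 2 s epochs)
  expect_lt(cm$values["CH3", "CH4"], 0.4)
})

test_that("generated recordings satisfy the container invariants", {
  m <- test_montage()
  g <- gen_microstate_eeg(duration_s = 5, montage = m, seed = 55)
  rec <- g$recording
  expect_s3_class(rec, "eeg_recording")
  expect_equal(rec$reference, "common_average")
  expect_lt(max(abs(colMeans(rec$data))), 1e-10)
  expect_equal(rec$segments, list(c(0L, n_samples(rec))))
  # templates mutually distinguishable
  cors <- abs(zolpiscope:::spatial_corr_matrix(t(g$truth$templates),
                                               t(g$truth$templates)))
  diag(cors) <- 0
  expect_lt(max(cors), 0.95)
  # durations respect the configured floor (the final segment may be
  # truncated by the end of the recording)
  d <- g$truth$segment_durations_ms
  expect_true(all(d[-length(d)] >= 40 - 1e-9))
})

test_that("planted paired effects are realized across subjects", {
  study <- gen_paired_study(n_subjects = 8, duration_s = 20,
                            labels = paste0("CH", 1:8), seed = 56)
  expect_equal(nrow(study$recordings), 16)
  # theta targets drop by exactly the planted effect in every subject
  expect_equal(study$truth$theta_T1 - study$truth$theta_T0,
               rep(-0.07, 8))
  # measured theta relative power drops in (nearly) every subject
  theta_of <- function(rec) {
    rp <- relative_power(welch_psd(rec), spectral_bands())
    rp$global$relative_power[rp$global$band == "theta"]
  }
  th <- vapply(study$recordings$recording, theta_of, numeric(1))
  d <- th[study$recordings$condition == "T1"] -
       th[study$recordings$condition == "T0"]
  expect_true(all(d < 0))
  # a sign-flip test on the realized effect reaches the n = 8 floor
  r <- perm_test_scalar(d, design = "within")
  expect_equal(r$p, 1 / 257)
  # outcome is the stated linear function of T0 coupling plus noise
  expect_equal(cor(study$truth$outcome, study$truth$coupling_T0) > 0.8, TRUE)
})

test_that("noiseless outcomes are perfectly recovered end to end", {
  study <- gen_paired_study(n_subjects = 8, duration_s = 6,
                            labels = paste0("CH", 1:6),
                            outcome_sd = 0, seed = 57)
  tb <- tibble::tibble(subject = study$truth$subject,
                       outcome = study$truth$outcome,
                       coupling = study$truth$coupling_T0)
  ev <- nested_loocv_svr(tb, features = "coupling", seed = 6)
  expect_gt(ev$cor, 0.99)
})
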