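test_that("surface Laplacian annihilates uniform fields and is linear", {
  m <- default_montage()
  uni <- eeg_recording(matrix(3.2, 59, 8), 250, labels = m$labels,
                       reference = "common_average")
  lap <- surface_laplacian(uni, m)
  expect_lt(max(abs(lap$data)), 1e-8)
  expect_equal(lap$reference, "laplacian")
  set.seed(13)
  x <- matrix(rnorm(59 * 5), 59, dimnames = list(m$labels, NULL))
  y <- matrix(rnorm(59 * 5), 59, dimnames = list(m$labels, NULL))
  L <- function(d) surface_laplacian(
    eeg_recording(d, 250, labels = m$labels, reference = "common_average"), m)$data
  expect_equal(L(x + y), L(x) + L(y), tolerance = 1e-9)
})

test_that("a focal topography keeps its peak and gains flanking sign reversal", {
  m <- default_montage()
  center <- m$positions["Cz", ]
  d <- as.numeric(m$positions %*% center)
  map <- exp(-8 * (1 - d))          # smooth bump centred on Cz
  rec <- eeg_recording(matrix(map - mean(map), 59, 3), 250, labels = m$labels,
                       reference = "common_average")
  lap <- surface_laplacian(rec, m)
  out <- lap$data[, 1]
  expect_equal(m$labels[which.max(out)], "Cz")
  # channels on the flanking ring flip sign
  flank <- m$labels[d > 0.2 & d < 0.6]
  expect_true(any(out[flank] < 0))
})

test_that("instantaneous phase of a 10 Hz sinusoid advances at 2*pi*10 rad/s", {
  fs <- 250
  t <- (0:(fs * 10 - 1)) / fs
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t)), fs,
                       reference = "laplacian")
  ph <- extract_phase(rec, "alpha")
  one <- ph$phases[1, 1, ]
  slope <- mean(diff(pracma_unwrap(one))) * fs
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01)
})

test_that("edge trimming and epoch tiling follow the per-segment contract", {
  set.seed(14)
  fs <- 250
  rec <- eeg_recording(matrix(rnorm(2 * fs * 10), 2), fs,
                       reference = "laplacian")
  ph <- extract_phase(rec, "alpha", epoch_s = 2, edge_trim = 0.10)
  expect_equal(dim(ph$phases)[1], 4)      # 10 s -> 8 s usable -> 4 epochs
  expect_equal(dim(ph$phases)[3], 500)
  two <- eeg_recording(matrix(rnorm(2 * fs * 10), 2), fs,
                       segments = list(c(0, 1250), c(1250, 2500)),
                       reference = "laplacian")
  ph2 <- extract_phase(two, "alpha")
  expect_equal(dim(ph2$phases)[1], 4)     # 2 + 2 epochs after per-segment trim
  short <- eeg_recording(matrix(rnorm(2 * fs * 2), 2), fs,
                         reference = "laplacian")
  expect_error(extract_phase(short, "alpha"), "epoch|short")
})

test_that("PLV satisfies its analytic fixed points", {
  set.seed(15)
  n <- 400
  ph <- array(0, c(3, 3, n))
  for (m in 1:3) {
    base <- runif(n, -pi, pi)
    ph[m, 1, ] <- base
    ph[m, 2, ] <- base + 1.1          # constant lag
    ph[m, 3, ] <- runif(n, -pi, pi)   # independent
  }
  ep <- structure(list(phases = ph, band = c(8, 13), band_name = "alpha",
                       epoch_s = 2, labels = c("a", "b", "c"), fs = 250),
                  class = "epoched_phase")
  cm <- plv(ep)
  expect_equal(cm$values["a", "b"], 1, tolerance = 1e-12)
  expect_equal(diag(cm$values), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(cm$values))
  expect_true(all(cm$values >= 0 & cm$values <= 1 + 1e-12))
  # adding a constant phase offset to one channel changes nothing
  ph2 <- ph; ph2[, 2, ] <- ph2[, 2, ] + 0.7
  ep2 <- ep; ep2$phases <- ph2
  expect_equal(plv(ep2)$values, cm$values, tolerance = 1e-12)
})

test_that("independent white phases give a small PLV at M = 150, N = 500", {
  set.seed(16)
  ph <- array(runif(150 * 2 * 500, -pi, pi), c(150, 2, 500))
  ep <- structure(list(phases = ph, band = c(8, 13), band_name = "alpha",
                       epoch_s = 2, labels = c("a", "b"), fs = 250),
                  class = "epoched_phase")
  expect_lt(plv(ep)$values["a", "b"], 0.1)
})

test_that("PLV equals the four-level nested-loop oracle on a toy instance", {
  set.seed(17)
  ph <- array(runif(2 * 3 * 40, -pi, pi), c(2, 3, 40))
  ep <- structure(list(phases = ph, band = c(8, 13), band_name = "alpha",
                       epoch_s = 2, labels = c("a", "b", "c"), fs = 250),
                  class = "epoched_phase")
  expect_equal(unname(plv(ep)$values), plv_oracle(ph), tolerance = 1e-12)
})

test_that("FCSCC is the mean connectivity over the component's edges", {
  vals <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  vals["a", "b"] <- vals["b", "a"] <- 0.7
  vals["b", "c"] <- vals["c", "b"] <- 0.4
  vals["c", "d"] <- vals["d", "c"] <- 0.6
  vals["a", "c"] <- vals["c", "a"] <- 0.2
  diag(vals) <- 1
  conn <- structure(list(values = vals, band = "alpha", labels = letters[1:4]),
                    class = "connectivity_matrix")
  expect_equal(mean_fcscc(conn, cbind("a", "b")), 0.7)
  expect_equal(mean_fcscc(conn, rbind(c("a", "c"), c("b", "c"), c("c", "d"))), 0.4)
  expect_error(mean_fcscc(conn, cbind(character(0), character(0))), "empty")
  # the all-pairs component equals the off-diagonal mean
  full <- all_edges(conn)
  off <- vals[upper.tri(vals)]
  expect_equal(mean_fcscc(conn, full), mean(off))
})

test_that("planted coupling strength is recovered monotonically by PLV", {
  strengths <- c(0, 0.3, 0.6, 0.9)
  mean_plv <- sapply(strengths, function(s) {
    mean(sapply(1:3, function(sd) {
      cpl <- data.frame(chan1 = "CH1", chan2 = "CH2", band = "alpha",
                        strength = s)
      r <- gen_oscillatory(c(delta = 0, theta = 0, alpha = 1, beta = 0,
                             gamma = 0),
                           coupling = cpl, duration_s = 40, fs = 250,
                           labels = paste0("CH", 1:8), seed = 100 + sd)
      r$reference <- "laplacian"
      band_plv(r, "alpha")$values["CH1", "CH2"]
    }))
  })
  expect_true(all(diff(mean_plv) > 0))
  expect_gt(mean_plv[4], 0.6)
})
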