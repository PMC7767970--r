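# Correlograms, shuffle nulls, covariance/coherence, CSD, pre/post spectra.

test_that("autocorrelogram of a 5 Hz tone: period 0.2 s, peak near 1", {
  fs <- 120; t <- (0:1199) / fs
  ac <- sliding_autocorrelogram(sin(2 * pi * 5 * t), fs)
  expect_close(ac$dominant_period_s, 0.2, tol = 1 / fs)
  expect_gt(ac$mean_peak, 0.95)
})

test_that("white noise and shuffled tones have near-zero correlogram peaks", {
  fs <- 120; n <- 2400
  set.seed(3)
  wn <- rnorm(n)
  ac <- sliding_autocorrelogram(wn, fs)
  # null scale for a 1 s window: ~3/sqrt(window samples)
  expect_lt(abs(ac$mean_peak), 3 / sqrt(fs))

  tone <- sin(2 * pi * 5 * (0:(n - 1)) / fs)
  ac_t <- sliding_autocorrelogram(tone, fs)
  ac_s <- sliding_autocorrelogram(shuffle_null(tone, seed = 5), fs)
  expect_gt(ac_t$mean_peak / max(abs(ac_s$mean_peak), 1e-3), 5)
})

test_that("shuffle_null preserves the amplitude histogram exactly", {
  set.seed(10)
  x <- rnorm(5000)
  s <- shuffle_null(x, seed = 2)
  expect_identical(sort(s), sort(x))
  expect_equal(mean(s), mean(x))
  expect_equal(stats::var(s), stats::var(x))
  r <- stats::acf(s, lag.max = 20, plot = FALSE)$acf[-1]
  expect_true(all(abs(r) < 3 / sqrt(length(x))))
})

test_that("cross-correlogram peak lag encodes phase offsets", {
  fs <- 120; t <- (0:1199) / fs
  a <- sin(2 * pi * 5 * t)
  self <- sliding_crosscorrelogram(a, a, fs)
  expect_equal(self$peak_lag_s, 0)
  expect_gt(self$mean_peak, 0.99)

  b <- sin(2 * pi * 5 * (t - 0.05))         # quarter period of 0.2 s
  cc <- sliding_crosscorrelogram(a, b, fs)
  # peak lags are defined modulo the period
  dev <- min(abs(cc$peak_lag_s - 0.05 + c(-1, 0, 1) * 0.2))
  expect_lte(dev, 1 / fs)
  expect_error(sliding_crosscorrelogram(a, b[1:100], fs), "length")
})

test_that("phase-lag recovery across phi and frequency", {
  fs <- 120
  for (f in c(4, 6, 10)) {
    for (phi in c(0, pi / 2, pi)) {
      fix <- generate_sto_movie(small_scene(
        n_clusters = 2, fs = fs, noise_sd = 2, seed = round(f * 10 + phi),
        freqs = c(f, f), phases = c(phi, 0)))
      tr <- lapply(0:1, function(g) gt_trace(fix, g))
      cc <- sliding_crosscorrelogram(tr[[1]], tr[[2]], fs)
      target <- phi / (2 * pi * f)
      dev <- min(abs(cc$peak_lag_s - target + (-2:2) / f))
      expect_lte(dev, 1 / fs + 1e-9)
    }
  }
})

test_that("windowed covariance: identical, anti-phase, independent pixels", {
  fs <- 120; t <- (0:599) / fs
  s <- sin(2 * pi * 5 * t)
  x <- array(0, c(600, 2, 2))
  x[, 1, 1] <- s; x[, 2, 1] <- s            # identical
  x[, 1, 2] <- -s                           # anti-phase
  set.seed(4)
  x[, 2, 2] <- rnorm(600, sd = 0.1)         # independent noise
  m <- sto_movie(x, fs, 17.86, origin = "dff")
  px <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  ca <- windowed_covariance(m, px, list(c(0, 5)), detrend_window_s = NULL)
  C <- ca$matrices[[1]]
  expect_equal(C[1, 2], C[1, 1], tolerance = 1e-10)
  expect_lt(C[1, 3], 0)
  # independent pixel: |cov| within 3 sd of the sampling distribution
  n <- 600
  sd_cov <- sqrt(stats::var(s) * stats::var(x[, 2, 2]) / (n - 1))
  expect_lt(abs(C[1, 4]), 3 * sd_cov)
  expect_error(windowed_covariance(m, px, list(c(0, 20))), "outside")
  expect_error(windowed_covariance(m, px[1, , drop = FALSE], list(c(0, 5))),
               "at least 2 pixels")
})

test_that("coherence image localizes the oscillating cluster", {
  fix <- generate_sto_movie(one_cluster_scene(frequency = 5, amplitude = 8,
                                              noise_sd = 5, bleach_tau = 100,
                                              frame = 24L))
  all_px <- cbind(rep(0:23, each = 24), rep(0:23, 24))
  ca <- windowed_covariance(fix$movie, all_px, list(c(0, 5), c(5, 10)))
  ci <- coherence_image(ca)
  top <- order(ci, decreasing = TRUE)[1:10]
  expect_true(all(fix$labels[top] >= 0))

  # max-over-windows: signal confined to window 2 dominates
  fs <- 40; t <- (0:399) / fs
  x <- array(rnorm(400 * 4, sd = 1e-3), c(400, 2, 2))
  late <- t >= 5
  x[late, 1, 1] <- x[late, 1, 1] + sin(2 * pi * 5 * t[late])
  x[late, 2, 1] <- x[late, 2, 1] + sin(2 * pi * 5 * t[late])
  m <- sto_movie(x, fs, 1, origin = "dff")
  px <- rbind(c(0, 0), c(1, 0))
  ca2 <- windowed_covariance(m, px, list(c(0, 5), c(5, 10)),
                             detrend_window_s = NULL)
  ci2 <- coherence_image(ca2)
  w2 <- (rowSums(abs(ca2$matrices[[2]])) - abs(diag(ca2$matrices[[2]])))
  expect_equal(ci2[1, 1], w2[1], tolerance = 1e-12)
})

test_that("cross PSD: self-consistency, anti-phase, distinct tones", {
  fs <- 120; t <- (0:1199) / fs
  a <- sin(2 * pi * 5 * t) + 0.1 * rnorm(1200)
  w <- welch_psd(a, fs)
  cp <- cross_psd(a, a, fs)
  expect_equal(cp$magnitude, w$psd, tolerance = 1e-12)
  expect_true(all(abs(cp$phase[w$psd > 1e-12]) < 1e-8))

  b <- -sin(2 * pi * 5 * t)
  cab <- cross_psd(sin(2 * pi * 5 * t), b, fs)
  tone <- which(cab$frequencies == 5)
  expect_close(abs(cab$phase[tone]), pi, tol = 1e-6)

  # different tones share no frequency content
  c2 <- sin(2 * pi * 9 * t)
  cx <- cross_psd(sin(2 * pi * 5 * t), c2, fs)
  auto <- welch_psd(sin(2 * pi * 5 * t), fs)
  expect_lt(cx$magnitude[tone], 1e-3 * auto$psd[tone])
  expect_error(cross_psd(a, b[1:600], fs), "length")
})

test_that("pre/post spectrum ratio: stationarity, gain, frequency shift", {
  fs <- 120; t <- (0:1199) / fs
  tone <- sin(2 * pi * 5 * t)
  r <- prepost_spectrum_ratio(tone, fs, c(4.5, 5.5))
  expect_close(r$ratio[r$frequencies == 5], 1, tol = 0.05)

  grow <- ifelse(t < 5, 1, 2) * sin(2 * pi * 5 * t)
  r2 <- prepost_spectrum_ratio(grow, fs, c(4.9, 5.1))
  expect_close(r2$ratio[r2$frequencies == 5], 4, tol = 0.4)

  shift <- ifelse(t < 5, sin(2 * pi * 4 * t), sin(2 * pi * 6 * t))
  r3 <- prepost_spectrum_ratio(shift, fs, c(4.9, 5.1))
  expect_gt(r3$ratio[r3$frequencies == 6], 1)
  expect_lt(r3$ratio[r3$frequencies == 4], 1)
  expect_equal(r3$peak_frequency_hz, 6)
  expect_error(prepost_spectrum_ratio(tone, fs, c(0.5, 1)), "before and after")
})

test_that("time-point correlation matrix and affine invariance", {
  fs <- 120; t <- (0:599) / fs
  a <- sin(2 * pi * 4 * t)
  traces <- cbind(a, -a, cos(2 * pi * 4 * t), rep(1, 600))
  tc <- timepoint_correlation_matrix(traces)
  expect_equal(tc$matrix[1, 2], -1, tolerance = 1e-10)
  expect_close(tc$matrix[1, 3], 0, tol = 1e-6)
  expect_true(is.na(tc$matrix[1, 4]))
  expect_equal(diag(tc$matrix), rep(1, 4), ignore_attr = TRUE)

  # affine rescaling of inputs changes nothing (correlation-based outputs)
  cc1 <- sliding_crosscorrelogram(a, traces[, 3], fs)
  cc2 <- sliding_crosscorrelogram(5 * a + 2, 0.1 * traces[, 3] - 7, fs)
  expect_equal(cc1$values, cc2$values, tolerance = 1e-10)
})

test_that("stimulation entrains clusters to a common frequency", {
  st <- stim_spec(onset_s = 4, entrained_frequency_hz = 6, power_gain = 1.5,
                  post_phase_rad = c(0, pi / 3))
  fix <- generate_sto_movie(small_scene(n_clusters = 2, freqs = c(4, 5),
                                        phases = c(0, 1), noise_sd = 2,
                                        stim = st, seed = 21L))
  fs <- 120
  for (g in 0:1) {
    tr <- gt_trace(fix, g)
    pre <- welch_psd(tr[1:(4 * fs)], fs)
    post <- welch_psd(tr[(5 * fs + 1):(10 * fs)], fs)
    f_pre <- pre$frequencies[which.max(pre$psd)]
    f_post <- post$frequencies[which.max(post$psd)]
    expect_close(f_pre, c(4, 5)[g + 1], tol = pre$df)
    expect_close(f_post, 6, tol = post$df)
  }
})
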