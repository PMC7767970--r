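# Welch PSD, band-power maps, normalization/thresholding, radial PSD decay.

test_that("welch_psd satisfies Parseval on tones and noise", {
  fs <- 120; t <- (0:1199) / fs
  s <- sin(2 * pi * 5 * t)
  w <- welch_psd(s, fs)
  expect_equal(w$frequencies[which.max(w$psd)], 5)
  expect_close(sum(w$psd) * w$df, 0.5, tol = 0.05)      # var(sin) = 1/2

  set.seed(2)
  n <- rnorm(12000, sd = 3)
  wn <- welch_psd(n, 1000)
  expect_close(sum(wn$psd) * wn$df, 9, tol = 0.9)       # within 10%

  wc <- welch_psd(rep(7, 1200), fs)
  expect_lt(sum(wc$psd), 1e-20)
  expect_error(welch_psd(s[1:50], fs), "at least 1 s")
})

test_that("band power map separates one 5 Hz cluster from noise floor", {
  fix <- generate_sto_movie(one_cluster_scene(frequency = 5, amplitude = 6,
                                              noise_sd = 5, bleach_tau = 100))
  img <- band_power_map(fix$movie)
  inside <- mean(img$band_power[fix$labels >= 0])
  outside <- mean(img$band_power[fix$labels < 0])
  expect_gt(inside / outside, 10)

  # independent per-pixel periodogram oracle on one footprint pixel
  d <- suppressWarnings(dff(fix$movie))
  i <- which(fix$labels >= 0)[5]
  tr <- d$data[, (i - 1) %% 32 + 1, (i - 1) %/% 32 + 1]
  pg <- Mod(fft(tr))^2 / length(tr)^2
  f <- (seq_along(tr) - 1) * 120 / length(tr)
  oracle_bp <- 2 * sum(pg[f >= 3 & f < 12 & f <= 60])
  expect_close(img$band_power[(i - 1) %% 32 + 1, (i - 1) %/% 32 + 1],
               oracle_bp, tol = 0.25 * oracle_bp)
})

test_that("out-of-band tones and silent movies give empty maps", {
  fix <- generate_sto_movie(one_cluster_scene(frequency = 20, amplitude = 6,
                                              noise_sd = 0, bleach_tau = Inf,
                                              fs = 120))
  # 20 Hz movie: nothing in the 3-12 band
  img <- band_power_map(fix$movie)
  expect_lt(max(img$band_power), 1e-8)      # leakage at machine level only

  z <- sto_movie(array(0, c(600, 8, 8)), 120, 17.86, origin = "dff")
  expect_true(all(band_power_map(z)$band_power == 0))
  expect_error(band_power_map(fix$movie, band = c(3, 80)), "Nyquist")
})

test_that("half-open band integration is exactly additive and scales as k^2", {
  fix <- generate_sto_movie(small_scene(noise_sd = 2, seed = 4L))
  m <- fix$movie
  whole <- band_power_map(m, c(3, 12))$band_power
  parts <- band_power_map(m, c(3, 7))$band_power +
    band_power_map(m, c(7, 12))$band_power
  expect_equal(whole, parts, tolerance = 1e-12)

  # scaling the oscillatory component by k scales band power by k^2
  d <- suppressWarnings(dff(m))
  d3 <- d; d3$data <- d$data * 3
  expect_equal(band_power_map(d3)$band_power,
               9 * band_power_map(d)$band_power, tolerance = 1e-10)
})

test_that("in-footprint PSD argmax recovers the cluster frequency", {
  for (fs in c(40, 120)) {
    for (f in c(4, 6, 10)) {
      fix <- generate_sto_movie(one_cluster_scene(frequency = f, fs = fs,
                                                  amplitude = 6, noise_sd = 5,
                                                  bleach_tau = 100,
                                                  seed = f + fs))
      px <- which(fix$labels >= 0)
      tr <- cluster_trace(fix$movie,
                          list(pixels = cbind(row(fix$labels)[px] - 1L,
                                              col(fix$labels)[px] - 1L)))
      w <- welch_psd(tr, fs)
      expect_close(w$frequencies[which.max(w$psd)], f, tol = w$df)
    }
  }
})

test_that("normalize_to_max: unit max, idempotent, order preserving", {
  set.seed(9)
  img <- psd_image(matrix(rexp(100), 10, 10), c(3, 12), 120, 17.86)
  n1 <- normalize_to_max(img)
  expect_equal(max(n1$band_power), 1)
  expect_equal(normalize_to_max(n1)$band_power, n1$band_power)
  expect_equal(cor(rank(as.vector(img$band_power)),
                   rank(as.vector(n1$band_power))), 1)
  zero <- psd_image(matrix(0, 4, 4), c(3, 12), 120, 17.86)
  expect_error(normalize_to_max(zero), "no positive")
})

test_that("quantile threshold: exact counts, containment, composability", {
  img <- psd_image(matrix(sample(1:100), 10, 10), c(3, 12), 120, 17.86)
  th <- threshold_quantile(img, 0.90)
  expect_identical(sum(th$mask), 10L)
  th_low <- threshold_quantile(img, 1e-9)
  expect_gte(sum(th_low$mask), 99L)

  fix <- generate_sto_movie(one_cluster_scene(frequency = 5, amplitude = 6,
                                              noise_sd = 5, bleach_tau = 100))
  bp <- band_power_map(fix$movie)
  thq <- threshold_quantile(bp, 0.90)       # footprint is < 10% of the frame
  expect_true(all(thq$mask[fix$labels >= 0]))

  flat <- psd_image(matrix(1, 5, 5), c(3, 12), 120, 17.86)
  expect_warning(tf <- threshold_quantile(flat, 0.9), "degenerate")
  expect_identical(sum(tf$mask), 0L)
})

test_that("z-score filter matches the normal tail and commutes with quantile", {
  set.seed(31)
  img <- psd_image(matrix(rnorm(40000), 200, 200), c(3, 12), 120, 17.86)
  z0 <- zscore_filter(img, 0)
  expect_equal(sum(z0$mask), sum(img$band_power > mean(img$band_power)))
  z2 <- zscore_filter(img, 2)
  expect_close(mean(z2$mask), pnorm(2, lower.tail = FALSE), tol = 0.005)

  a <- zscore_filter(threshold_quantile(img, 0.9), 1)
  b <- threshold_quantile(zscore_filter(img, 1), 0.9)
  expect_identical(a$mask, b$mask)
})

test_that("psd_vs_distance: flat, exponential and monotone cases", {
  uni <- psd_image(matrix(1 + 1e-9 * matrix(runif(4096), 64), 64, 64),
                   c(3, 12), 120, 10)
  pu <- psd_vs_distance(uni, c(31.5, 31.5))
  expect_true(pu$censored)

  # map exp(-r / lambda): half-max at lambda * ln 2
  lambda <- 120
  r <- sqrt((row(matrix(0, 81, 81)) - 41)^2 +
              (col(matrix(0, 81, 81)) - 41)^2) * 10   # 10 um pitch
  em <- psd_image(exp(-r / lambda), c(3, 12), 120, 10)
  pe <- psd_vs_distance(em, c(40, 40))
  expect_close(pe$half_max_distance_um, lambda * log(2), tol = 10)
  # per-pixel exp(-r/lambda) vs r is monotone but nonlinear: strongly
  # negative Pearson correlation, not -1
  expect_lt(pe$correlation, -0.5)
})
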