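# Shared fixture builders. All fixtures are generated in code; small frames
# (32-64 px) keep the suite fast while preserving the stated physiology
# (frequencies, amplitudes, dye sensitivity, pixel pitch).

# standard small two-cluster scene; noiseless unless stated
small_scene <- function(n_clusters = 2, frame = 64L, fs = 120, dur = 10,
                        noise_sd = 5, amplitude = 6, seed = 1L,
                        freqs = c(4, 6, 10, 8), phases = seq_len(4),
                        bleach_tau = 100, stim = NULL) {
  pos <- list(c(14, 14), c(48, 46), c(16, 50), c(50, 14))
  cls <- lapply(seq_len(n_clusters), function(i)
    cluster_spec(pos[[i]] * frame / 64, freqs[i], amplitude,
                 phase_rad = phases[i]))
  scene_config(frame_size = c(frame, frame), frame_rate = fs,
               duration_s = dur, clusters = cls, noise_sd = noise_sd,
               bleach_tau_s = bleach_tau, stim = stim, seed = seed)
}

# one centred cluster in a small frame
one_cluster_scene <- function(frequency = 5, amplitude = 10, frame = 32L,
                              fs = 120, dur = 10, noise_sd = 0,
                              bleach_tau = Inf, seed = 1L, pitch = 17.86) {
  cl <- cluster_spec(c((frame - 1) / 2, (frame - 1) / 2), frequency, amplitude,
                     check_band = FALSE)
  scene_config(frame_size = c(frame, frame), frame_rate = fs,
               duration_s = dur, clusters = list(cl), noise_sd = noise_sd,
               bleach_tau_s = bleach_tau, pixel_pitch = pitch, seed = seed)
}

# the standard masking recipe: max-normalize, 90% quantile + z >= 2
standard_mask <- function(movie, band = c(3, 12)) {
  img <- band_power_map(movie, band)
  zscore_filter(threshold_quantile(normalize_to_max(img), 0.9), 2)
}

# ground-truth cluster trace from a fixture, optionally detrended (slow
# bleach residue otherwise correlates every trace with every other)
gt_trace <- function(fix, g, detrend = TRUE) {
  px <- which(fix$labels == g)
  tr <- cluster_trace(fix$movie,
                      list(pixels = cbind(row(fix$labels)[px] - 1L,
                                          col(fix$labels)[px] - 1L)))
  if (detrend) detrend_trace(tr, fix$movie$frame_rate) else tr
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %.3g", actual, expected, tol))
}
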