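# Temporal-structure analyses: sliding auto-/cross-correlograms, shuffle
# nulls, windowed covariance and coherence images, cross-power spectral
# density, pre/post-stimulation spectral ratios, and time-point correlation
# matrices.

window_starts <- function(n, w, step) {
  if (n < w + step) stop("trace shorter than two sliding windows")
  seq(1L, n - w + 1L, by = step)
}

first_positive_peak <- function(r) {
  # first local maximum at non-zero lag with positive value
  k <- length(r)
  for (i in 2:(k - 1L)) {
    if (r[i] > 0 && r[i] >= r[i - 1L] && r[i] >= r[i + 1L]) return(i)
  }
  if (k >= 2L && r[k] > 0 && r[k] >= r[k - 1L]) return(k)
  NA_integer_
}

#' Sliding-window autocorrelogram
#'
#' Normalized autocorrelation computed in sliding windows (default 1 s,
#' half-window step), averaged across windows. Reports the dominant period
#' (lag of the first positive non-zero-lag peak of the mean correlogram)
#' and the per-window peak height (mean +/- sd). Zero-variance windows are
#' skipped with a warning.
#'
#' @param trace Numeric vector or [ephys_trace()].
#' @param sample_rate Hz (from the trace if an [ephys_trace()]).
#' @param window_s Window length, seconds.
#' @return A `correlogram` list: `lags` (s), `values` (mean correlogram),
#'   `dispersion` (sd across windows), `per_window`, `dominant_period_s`,
#'   `mean_peak`, `peak_sd`, `n_windows`.
#' @export
sliding_autocorrelogram <- function(trace, sample_rate = NULL, window_s = 1) {
  if (inherits(trace, "ephys_trace")) {
    sample_rate <- trace$sample_rate
    trace <- trace$samples
  }
  if (is.null(sample_rate)) stop("sample_rate required")
  w <- round(window_s * sample_rate)
  step <- max(1L, w %/% 2L)
  starts <- window_starts(length(trace), w, step)
  maxlag <- w %/% 2L
  acfs <- matrix(NA_real_, maxlag + 1L, length(starts))
  skipped <- 0L
  for (s in seq_along(starts)) {
    seg <- trace[starts[s] + 0:(w - 1L)]
    if (stats::sd(seg) == 0) { skipped <- skipped + 1L; next }
    # overlap-normalized autocorrelation (no taper: a pure tone keeps
    # peak height ~1 at its period)
    acfs[, s] <- vapply(0:maxlag, function(k) {
      if (k == 0L) return(1)
      a <- seg[1:(w - k)]; b <- seg[(1L + k):w]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)
    }, numeric(1))
  }
  if (skipped) warning(skipped, " constant window(s) skipped (zero variance)")
  ok <- colSums(is.na(acfs)) == 0L
  if (!any(ok)) stop("no usable windows")
  vals <- rowMeans(acfs[, ok, drop = FALSE])
  disp <- apply(acfs[, ok, drop = FALSE], 1L, stats::sd)
  peaks <- apply(acfs[, ok, drop = FALSE], 2L, function(r) {
    i <- first_positive_peak(r)
    if (is.na(i)) c(NA_real_, NA_real_) else c((i - 1L) / sample_rate, r[i])
  })
  pk_mean <- first_positive_peak(vals)
  structure(list(lags = (0:maxlag) / sample_rate, values = vals,
                 dispersion = disp,
                 per_window = acfs[, ok, drop = FALSE],
                 window_s = window_s, type = "auto",
                 dominant_period_s = if (is.na(pk_mean)) NA_real_
                 else (pk_mean - 1L) / sample_rate,
                 mean_peak = mean(peaks[2L, ], na.rm = TRUE),
                 peak_sd = stats::sd(peaks[2L, ], na.rm = TRUE),
                 n_windows = sum(ok)),
            class = "correlogram")
}

#' Temporal shuffle null for a trace
#'
#' Random permutation of the time samples: preserves the amplitude
#' histogram exactly while destroying autocorrelation.
#'
#' @param trace Numeric vector or [ephys_trace()].
#' @param seed Integer RNG seed.
#' @return Shuffled trace of the same type.
#' @export
shuffle_null <- function(trace, seed = 1L) {
  if (inherits(trace, "ephys_trace"))
    return(ephys_trace(shuffle_null(trace$samples, seed), trace$sample_rate))
  if (!length(trace)) stop("empty trace")
  with_seed(seed, sample(trace))
}

#' Sliding-window cross-correlogram
#'
#' Normalized cross-correlation between two traces of equal length and
#' rate, per sliding window, at lags up to half the window. A positive lag
#' means the second trace must be advanced to match the first. Reports the
#' per-window peak value (mean across windows) and the peak lag of the mean
#' correlogram.
#'
#' @param trace_a,trace_b Numeric vectors of equal length (downsample
#'   electrophysiology first; see [downsample_ephys()]).
#' @param sample_rate Hz.
#' @param window_s Window length, seconds (1 s for imaging/ephys agreement,
#'   2 s for cluster-coherence figures).
#' @return A `correlogram` list with signed `lags`, mean `values`,
#'   `dispersion`, `per_window`, `mean_peak`, `peak_sd`, `peak_lag_s`,
#'   `n_windows`.
#' @export
sliding_crosscorrelogram <- function(trace_a, trace_b, sample_rate,
                                     window_s = 1) {
  if (inherits(trace_a, "ephys_trace") || inherits(trace_b, "ephys_trace"))
    stop("pass plain numeric traces at a common rate ",
         "(use downsample_ephys() on the electrophysiology first)")
  if (length(trace_a) != length(trace_b))
    stop("traces differ in length; resample to a common rate first ",
         "(downsample_ephys)")
  w <- round(window_s * sample_rate)
  step <- max(1L, w %/% 2L)
  starts <- window_starts(length(trace_a), w, step)
  maxlag <- w %/% 2L
  lags <- (-maxlag):maxlag
  cc <- matrix(NA_real_, length(lags), length(starts))
  for (s in seq_along(starts)) {
    a <- trace_a[starts[s] + 0:(w - 1L)]
    b <- trace_b[starts[s] + 0:(w - 1L)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    cc[, s] <- vapply(lags, function(k) {
      if (k >= 0) {
        ai <- 1:(w - k); bi <- (1L + k):w
      } else {
        ai <- (1L - k):w; bi <- 1:(w + k)
      }
      if (stats::sd(a[ai]) == 0 || stats::sd(b[bi]) == 0) return(NA_real_)
      stats::cor(a[ai], b[bi])
    }, numeric(1))
  }
  ok <- colSums(is.na(cc)) == 0L
  if (!any(ok)) stop("no usable windows (zero variance)")
  vals <- rowMeans(cc[, ok, drop = FALSE])
  peaks <- apply(cc[, ok, drop = FALSE], 2L, max)
  # periodic signals tie across whole periods: report the smallest |lag|
  near_max <- which(vals >= max(vals) - 1e-9)
  peak_lag <- near_max[which.min(abs(lags[near_max]))]
  structure(list(lags = lags / sample_rate, values = vals,
                 dispersion = apply(cc[, ok, drop = FALSE], 1L, stats::sd),
                 per_window = cc[, ok, drop = FALSE],
                 window_s = window_s, type = "cross",
                 mean_peak = mean(peaks), peak_sd = stats::sd(peaks),
                 peak_lag_s = lags[peak_lag] / sample_rate,
                 n_windows = sum(ok)),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram:%s> %d window(s) of %g s, mean peak %.3f +/- %.3f",
              x$type, x$n_windows, x$window_s, x$mean_peak,
              if (is.na(x$peak_sd)) 0 else x$peak_sd))
  if (x$type == "auto" && !is.na(x$dominant_period_s))
    cat(sprintf(", dominant period %.4g s", x$dominant_period_s))
  if (x$type == "cross") cat(sprintf(", peak lag %.4g s", x$peak_lag_s))
  cat("\n")
  invisible(x)
}

#' Windowed pixel-by-pixel covariance
#'
#' Covariance matrices of detrended dF/F pixel traces over a set of time
#' windows (e.g. baseline / stimulation / post-stimulation / recovery).
#' Display-normalized copies rescale covariance to `[0, 1]` jointly across
#' windows (default) or per window; raw matrices are retained.
#'
#' @param movie An [sto_movie()].
#' @param pixels 0-based (row, col) matrix of analyzed pixels (>= 2).
#' @param windows List of `c(t0, t1)` second pairs (half-open).
#' @param detrend_window_s Running-median detrend window (0.25 s default);
#'   `NULL` skips detrending.
#' @param normalization `"joint"` or `"per-window"`.
#' @return A `covariance_analysis` list: `windows`, `matrices` (raw),
#'   `normalized`, `pixels`, `frame_size`.
#' @export
windowed_covariance <- function(movie, pixels, windows,
                                detrend_window_s = 0.25,
                                normalization = c("joint", "per-window")) {
  stopifnot(inherits(movie, "sto_movie"))
  normalization <- match.arg(normalization)
  if (!is.matrix(pixels) || nrow(pixels) < 2L)
    stop("need at least 2 pixels for covariance analysis")
  d <- dim(movie$data)
  if (movie$origin %in% c("raw", "bleach-corrected"))
    movie <- suppressWarnings(dff(movie))
  x <- matrix(movie$data, d[1L], d[2L] * d[3L])
  idx <- pixels[, 1] + 1L + pixels[, 2] * d[2L]
  traces <- x[, idx, drop = FALSE]
  if (!is.null(detrend_window_s))
    traces <- apply(traces, 2L, detrend_trace, sample_rate = movie$frame_rate,
                    window_s = detrend_window_s)
  t <- (seq_len(d[1L]) - 1L) / movie$frame_rate
  mats <- lapply(windows, function(wd) {
    stopifnot(length(wd) == 2L, wd[1] < wd[2])
    sel <- t >= wd[1] & t < wd[2]
    if (sum(sel) < 2L)
      stop(sprintf("window [%g, %g) s holds fewer than 2 frames", wd[1], wd[2]))
    if (wd[1] < 0 || wd[2] > movie_duration(movie) + 1e-9)
      stop(sprintf("window [%g, %g) s outside the recording", wd[1], wd[2]))
    stats::cov(traces[sel, , drop = FALSE])
  })
  norm <- if (normalization == "joint") {
    lo <- min(vapply(mats, min, numeric(1)))
    hi <- max(vapply(mats, max, numeric(1)))
    lapply(mats, function(m) if (hi > lo) (m - lo) / (hi - lo) else m * 0)
  } else {
    lapply(mats, function(m) {
      lo <- min(m); hi <- max(m)
      if (hi > lo) (m - lo) / (hi - lo) else m * 0
    })
  }
  structure(list(windows = windows, matrices = mats, normalized = norm,
                 pixels = pixels, frame_size = d[2:3],
                 normalization = normalization),
            class = "covariance_analysis")
}

#' Coherence image from windowed covariance
#'
#' For each analyzed pixel, takes the maximum across windows of its mean
#' absolute off-diagonal covariance with the other pixels, rendered on the
#' frame grid (unanalyzed pixels are `NA`).
#'
#' @param cov_analysis A `covariance_analysis` from [windowed_covariance()].
#' @return Numeric matrix of the frame size.
#' @export
coherence_image <- function(cov_analysis) {
  stopifnot(inherits(cov_analysis, "covariance_analysis"))
  m <- nrow(cov_analysis$pixels)
  if (m < 2L) stop("coherence image needs at least 2 analyzed pixels")
  per_window <- vapply(cov_analysis$matrices, function(C) {
    (rowSums(abs(C)) - abs(diag(C))) / (m - 1L)
  }, numeric(m))
  score <- apply(matrix(per_window, nrow = m), 1L, max)
  img <- matrix(NA_real_, cov_analysis$frame_size[1], cov_analysis$frame_size[2])
  img[cbind(cov_analysis$pixels[, 1] + 1L, cov_analysis$pixels[, 2] + 1L)] <- score
  img
}

#' Welch cross-power spectral density
#'
#' Magnitude and phase of the Welch cross-spectrum of two traces (same
#' segmentation, window and detrend as [welch_psd()]). For identical inputs
#' the magnitude equals the PSD bin-by-bin with zero phase.
#'
#' @param trace_a,trace_b Equal-length numeric vectors.
#' @param sample_rate Hz.
#' @param segment_s,overlap,detrend Welch parameters.
#' @return List with `frequencies`, `magnitude`, `phase` (radians), complex
#'   `csd` and `df`.
#' @export
cross_psd <- function(trace_a, trace_b, sample_rate, segment_s = 1,
                      overlap = 0.5, detrend = "linear") {
  if (length(trace_a) != length(trace_b))
    stop("traces differ in length; resample to a common rate first")
  wf <- welch_fft_stack(cbind(trace_a, trace_b), sample_rate, segment_s,
                        overlap, detrend)
  cross <- wf$stack[, 1L, , drop = FALSE] * Conj(wf$stack[, 2L, , drop = FALSE])
  pxy <- apply(cross, 1L, mean) * wf$scale
  pxy <- drop(one_sided_double(matrix(pxy, ncol = 1L), wf$nper))
  list(frequencies = wf$frequencies, magnitude = Mod(pxy),
       phase = Arg(pxy), csd = pxy,
       df = wf$frequencies[2L] - wf$frequencies[1L])
}

#' Post- vs pre-stimulation PSD ratio
#'
#' Welch PSD of a matched-duration window after the stimulation train
#' divided by the PSD of the window just before it, per frequency bin.
#'
#' @param trace Numeric vector.
#' @param sample_rate Hz.
#' @param stim_window `c(t0, t1)` seconds covering the stimulation train.
#' @param window_s Pre/post comparison window (default 2 s).
#' @param segment_s Welch segment; defaults to the full comparison window
#'   (a single 0.5 Hz-resolution periodogram per window), so that
#'   neighbouring pre/post oscillation frequencies land in disjoint bins
#'   instead of leaking into each other's ratio.
#' @param overlap Welch overlap (only relevant when `segment_s < window_s`).
#' @param window Taper for the two periodograms. The default `"boxcar"`
#'   keeps an oscillation's power in its own bin: a per-bin *ratio*
#'   amplifies taper leakage (leaked numerator over a bare noise-floor
#'   denominator), which with a Hann taper can move the ratio peak off the
#'   true frequency by one bin.
#' @return List with `frequencies`, `ratio`, `peak_ratio`,
#'   `peak_frequency_hz`, `psd_pre`, `psd_post`.
#' @export
prepost_spectrum_ratio <- function(trace, sample_rate, stim_window,
                                   window_s = 2, segment_s = window_s,
                                   overlap = 0.5, window = "boxcar") {
  stopifnot(length(stim_window) == 2L, stim_window[1] < stim_window[2])
  n <- length(trace)
  t_end <- n / sample_rate
  if (stim_window[1] - window_s < -1e-9 ||
      stim_window[2] + window_s > t_end + 1e-9)
    stop(sprintf("need %g s of data both before and after the stimulation window",
                 window_s))
  idx <- function(t0, t1) {
    i0 <- floor(t0 * sample_rate) + 1L
    i1 <- min(n, floor(t1 * sample_rate))
    trace[i0:i1]
  }
  pre <- idx(stim_window[1] - window_s, stim_window[1])
  post <- idx(stim_window[2], stim_window[2] + window_s)
  ppre <- welch_psd(pre, sample_rate, segment_s, overlap, window = window)
  ppost <- welch_psd(post, sample_rate, segment_s, overlap, window = window)
  ratio <- ppost$psd / ppre$psd
  ratio[!is.finite(ratio)] <- NA_real_
  cand <- which(ppre$frequencies > 0 & is.finite(ratio))
  pk <- cand[which.max(ratio[cand])]
  list(frequencies = ppre$frequencies, ratio = ratio,
       peak_ratio = ratio[pk], peak_frequency_hz = ppre$frequencies[pk],
       psd_pre = ppre$psd, psd_post = ppost$psd)
}

#' Time-point correlation matrix between traces
#'
#' Pearson correlation between all pairs of (cluster-average) traces within
#' a time window. Zero-variance traces yield `NA` for their pairs.
#'
#' @param traces Numeric matrix (time x traces) or list of equal-length
#'   vectors.
#' @param sample_rate Hz; required when `window` is given in seconds.
#' @param window Optional `c(t0, t1)` seconds (half-open); default full
#'   length.
#' @return List with `matrix` (symmetric, unit diagonal) and `pairs` (long
#'   table of coefficients).
#' @export
timepoint_correlation_matrix <- function(traces, sample_rate = NULL,
                                         window = NULL) {
  if (is.list(traces)) {
    len <- vapply(traces, length, integer(1))
    if (length(unique(len)) != 1L) stop("traces must have equal length")
    traces <- do.call(cbind, traces)
  }
  stopifnot(is.matrix(traces))
  if (ncol(traces) < 2L) stop("need at least 2 traces")
  if (!is.null(window)) {
    if (is.null(sample_rate)) stop("sample_rate required with a time window")
    t <- (seq_len(nrow(traces)) - 1L) / sample_rate
    sel <- t >= window[1] & t < window[2]
    if (sum(sel) < 3L) stop("window holds fewer than 3 samples")
    traces <- traces[sel, , drop = FALSE]
  }
  k <- ncol(traces)
  sds <- apply(traces, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(traces))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  diag(cm) <- 1
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  list(matrix = cm,
       pairs = data.frame(a = pairs[, 1] - 1L, b = pairs[, 2] - 1L,
                          r = cm[pairs]))
}
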