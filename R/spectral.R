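# Per-pixel spectral mapping: Welch PSD, band-power images, normalization,
# thresholding, and PSD-vs-distance profiles.
#
# Welch defaults throughout: 1 s segments (1 Hz resolution at all supported
# frame rates), 50% overlap, periodic Hann window, linear detrend per
# segment, one-sided density scaling (integrated PSD ~ trace variance).

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# Segment-wise windowed FFTs for one or many traces. x: vector or
# (time x traces) matrix. Returns one-sided frequencies, the complex FFT
# stack (freq x traces x segments) and the density scale factor.
welch_fft_stack <- function(x, sample_rate, segment_s = 1, overlap = 0.5,
                            detrend = c("linear", "constant", "none"),
                            window = c("hann", "boxcar")) {
  detrend <- match.arg(detrend)
  window <- match.arg(window)
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  nper <- round(segment_s * sample_rate)
  if (nper < 4L) stop("Welch segment must span at least 4 samples")
  if (n < nper)
    stop(sprintf(paste0("trace of %.4g s is shorter than one Welch segment; ",
                        "at least %.4g s of data required"),
                 n / sample_rate, nper / sample_rate))
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- if (window == "hann") hann_window(nper) else rep(1, nper)
  basis <- switch(detrend,
                  linear = cbind(1, seq_len(nper)),
                  constant = matrix(1, nper, 1L),
                  none = NULL)
  proj <- if (!is.null(basis)) solve(crossprod(basis), t(basis))
  nfreq <- nper %/% 2L + 1L
  stack <- array(0i, c(nfreq, ncol(x), length(starts)))
  for (s in seq_along(starts)) {
    seg <- x[starts[s] + 0:(nper - 1L), , drop = FALSE]
    if (!is.null(basis)) seg <- seg - basis %*% (proj %*% seg)
    ft <- stats::mvfft(seg * w)
    stack[, , s] <- ft[seq_len(nfreq), , drop = FALSE]
  }
  list(frequencies = (seq_len(nfreq) - 1L) * sample_rate / nper,
       stack = stack, nper = nper,
       scale = 1 / (sample_rate * sum(w^2)))
}

one_sided_double <- function(p, nper) {
  nfreq <- nrow(p)
  dbl <- rep(2, nfreq)
  dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[nfreq] <- 1     # Nyquist bin not doubled
  p * dbl
}

#' Welch power spectral density of a trace
#'
#' @param trace Numeric vector or [ephys_trace()].
#' @param sample_rate Hz (taken from the trace when it is an
#'   [ephys_trace()]).
#' @param segment_s Segment length in seconds (default 1 s -> 1 Hz
#'   resolution).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param detrend Per-segment detrending: `"linear"` (default),
#'   `"constant"`, or `"none"`.
#' @param window Segment taper, `"hann"` (default) or `"boxcar"`.
#' @return List with `frequencies` (Hz), `psd` (one-sided density, units of
#'   input^2 / Hz) and `df` (bin width). `sum(psd) * df` approximates the
#'   trace variance.
#' @export
welch_psd <- function(trace, sample_rate = NULL, segment_s = 1,
                      overlap = 0.5, detrend = "linear", window = "hann") {
  if (inherits(trace, "ephys_trace")) {
    sample_rate <- trace$sample_rate
    trace <- trace$samples
  }
  if (is.null(sample_rate)) stop("sample_rate required")
  wf <- welch_fft_stack(trace, sample_rate, segment_s, overlap, detrend,
                        window)
  p <- apply(abs(wf$stack)^2, 1L, mean) * wf$scale
  p <- drop(one_sided_double(matrix(p, ncol = 1L), wf$nper))
  list(frequencies = wf$frequencies, psd = p,
       df = wf$frequencies[2L] - wf$frequencies[1L])
}

#' Construct a PSD image object
#'
#' Container for a per-pixel band-power map and its normalization /
#' threshold state. Usually produced by [band_power_map()].
#'
#' @param band_power Numeric matrix, (dF/F)^2.
#' @param band `c(f_lo, f_hi)` Hz.
#' @param frame_rate,pixel_pitch Movie metadata carried along.
#' @param normalization,mask,threshold_quantile,z_min,segment_s,overlap
#'   Processing state.
#' @return A `psd_image` list.
#' @export
psd_image <- function(band_power, band, frame_rate, pixel_pitch,
                      normalization = "raw", mask = NULL,
                      threshold_quantile = NULL, z_min = NULL,
                      segment_s = 1, overlap = 0.5) {
  stopifnot(is.matrix(band_power))
  structure(list(band_power = band_power, band = band,
                 frame_rate = frame_rate, pixel_pitch = pixel_pitch,
                 normalization = normalization, mask = mask,
                 threshold_quantile = threshold_quantile, z_min = z_min,
                 segment_s = segment_s, overlap = overlap),
            class = "psd_image")
}

#' @export
print.psd_image <- function(x, ...) {
  cat(sprintf("<psd_image> %d x %d px, band [%g, %g) Hz, %s%s\n",
              nrow(x$band_power), ncol(x$band_power), x$band[1], x$band[2],
              x$normalization,
              if (!is.null(x$mask)) sprintf(", %d px masked in", sum(x$mask))
              else ""))
  invisible(x)
}

#' Per-pixel band power map
#'
#' Computes each pixel's Welch PSD on its dF/F trace and integrates it over
#' a frequency band (half-open `[f_lo, f_hi)`, so adjacent sub-bands add
#' exactly). Raw or bleach-corrected movies are converted to dF/F (temporal
#' mean baseline) first.
#'
#' @param movie An [sto_movie()].
#' @param band `c(f_lo, f_hi)` in Hz, inside `(0, Nyquist]`; default the
#'   3-12 Hz subthreshold band.
#' @param segment_s,overlap Welch parameters.
#' @param chunk Pixels processed per FFT block (memory knob).
#' @return A `psd_image` with `band_power` in (dF/F)^2.
#' @export
band_power_map <- function(movie, band = c(3, 12), segment_s = 1,
                           overlap = 0.5, chunk = 4096L) {
  stopifnot(inherits(movie, "sto_movie"))
  nyq <- movie$frame_rate / 2
  if (band[1] < 0 || band[2] <= band[1])
    stop("band must be an increasing pair of non-negative frequencies")
  if (band[2] > nyq + 1e-9)
    stop(sprintf("band upper edge %.6g Hz exceeds the Nyquist frequency %.6g Hz",
                 band[2], nyq))
  if (movie_duration(movie) < segment_s)
    stop("movie shorter than one Welch segment")
  if (movie$origin %in% c("raw", "bleach-corrected"))
    movie <- suppressWarnings(dff(movie))
  d <- dim(movie$data)
  x <- matrix(movie$data, d[1L], d[2L] * d[3L])
  npx <- ncol(x)
  bp <- numeric(npx)
  for (from in seq(1L, npx, by = chunk)) {
    to <- min(from + chunk - 1L, npx)
    wf <- welch_fft_stack(x[, from:to, drop = FALSE], movie$frame_rate,
                          segment_s, overlap)
    p <- apply(abs(wf$stack)^2, c(1L, 2L), mean) * wf$scale
    p <- one_sided_double(p, wf$nper)
    df <- wf$frequencies[2L] - wf$frequencies[1L]
    sel <- wf$frequencies >= band[1] & wf$frequencies < band[2]
    bp[from:to] <- colSums(p[sel, , drop = FALSE]) * df
  }
  psd_image(matrix(bp, d[2L], d[3L]), band, movie$frame_rate,
            movie$pixel_pitch, segment_s = segment_s, overlap = overlap)
}

#' Normalize a PSD image to its maximal pixel
#'
#' @param img A `psd_image` with at least one positive value.
#' @return The image divided by its maximum (`normalization =
#'   "max-normalized"`); idempotent.
#' @export
normalize_to_max <- function(img) {
  stopifnot(inherits(img, "psd_image"))
  m <- max(img$band_power, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize: no positive band power value")
  img$band_power <- img$band_power / m
  img$normalization <- "max-normalized"
  img
}

#' Threshold a PSD image at a sample quantile
#'
#' Retains pixels with band power strictly above the `q` quantile
#' (linear-interpolation sample quantile) of all in-frame values; the
#' resulting mask is intersected with any existing mask.
#'
#' @param img A `psd_image`.
#' @param q Quantile in (0, 1); default 0.90, the noise-elimination
#'   threshold of the mapping pipeline.
#' @return The image with its `mask` updated.
#' @export
threshold_quantile <- function(img, q = 0.90) {
  stopifnot(inherits(img, "psd_image"))
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  v <- img$band_power[is.finite(img$band_power)]
  if (length(unique(v)) <= 1L) {
    warning("degenerate all-equal PSD image: empty mask")
    new_mask <- matrix(FALSE, nrow(img$band_power), ncol(img$band_power))
  } else {
    thr <- stats::quantile(v, q, type = 7, names = FALSE)
    new_mask <- img$band_power > thr & is.finite(img$band_power)
  }
  img$mask <- if (is.null(img$mask)) new_mask else img$mask & new_mask
  img$threshold_quantile <- q
  img
}

#' Z-score filter on a PSD image
#'
#' Retains pixels whose band-power z-score relative to all in-frame pixels
#' is at least `z_min`; intersected with any existing mask, so it composes
#' with [threshold_quantile()] in either order.
#'
#' @param img A `psd_image`.
#' @param z_min Minimal z-score (default 2).
#' @return The image with its `mask` updated.
#' @export
zscore_filter <- function(img, z_min = 2) {
  stopifnot(inherits(img, "psd_image"))
  v <- img$band_power[is.finite(img$band_power)]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    warning("zero variance across pixels: empty mask")
    new_mask <- matrix(FALSE, nrow(img$band_power), ncol(img$band_power))
  } else {
    z <- (img$band_power - mean(v)) / s
    new_mask <- z >= z_min & is.finite(img$band_power)
  }
  img$mask <- if (is.null(img$mask)) new_mask else img$mask & new_mask
  img$z_min <- z_min
  img
}

#' Radial decay of normalized band power around a point
#'
#' Bins the per-pixel normalized band power by distance from a centre
#' (typically the injection centre) and reports the binned profile, the
#' distance at which it first falls below half its peak, and the Pearson
#' correlation between per-pixel distance and normalized power.
#'
#' @param img A `psd_image`; masked images use masked-in pixels only.
#' @param center Pixel coordinates `c(row, col)`, 0-based.
#' @param bin_width_um Radial bin width; default one pixel pitch.
#' @return List with `table` (`distance_um`, `mean_psd`, `n_pixels`),
#'   `half_max_distance_um` (`NA` when the profile never falls below
#'   half-peak within the field; see `censored`), `censored`, and
#'   `correlation`.
#' @export
psd_vs_distance <- function(img, center, bin_width_um = NULL) {
  stopifnot(inherits(img, "psd_image"))
  bp <- img$band_power
  if (center[1] < 0 || center[1] > nrow(bp) - 1L ||
      center[2] < 0 || center[2] > ncol(bp) - 1L)
    stop("center outside the frame")
  keep <- if (!is.null(img$mask)) img$mask & is.finite(bp) else is.finite(bp)
  if (!any(keep)) stop("no pixels to profile (all masked out)")
  bin_width_um <- bin_width_um %||% img$pixel_pitch
  v <- bp[keep] / max(bp[keep])
  rows <- row(bp)[keep] - 1L; cols <- col(bp)[keep] - 1L
  dist_um <- sqrt((rows - center[1])^2 + (cols - center[2])^2) * img$pixel_pitch
  bin <- floor(dist_um / bin_width_um)
  prof <- tapply(v, bin, mean)
  tab <- data.frame(distance_um = (as.numeric(names(prof)) + 0.5) * bin_width_um,
                    mean_psd = as.numeric(prof),
                    n_pixels = as.integer(table(bin)))
  peak_i <- which.max(tab$mean_psd)
  half <- tab$mean_psd[peak_i] / 2
  below <- which(tab$mean_psd < half & seq_len(nrow(tab)) > peak_i)
  if (length(below)) {
    j <- below[1L]
    x0 <- tab$distance_um[j - 1L]; x1 <- tab$distance_um[j]
    y0 <- tab$mean_psd[j - 1L]; y1 <- tab$mean_psd[j]
    hmd <- x0 + (y0 - half) / (y0 - y1) * (x1 - x0)
    censored <- FALSE
  } else {
    hmd <- NA_real_
    censored <- TRUE
  }
  corr <- if (stats::sd(dist_um) > 0 && stats::sd(v) > 0)
    stats::cor(dist_um, v) else NA_real_
  list(table = tab, half_max_distance_um = hmd, censored = censored,
       correlation = corr)
}
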