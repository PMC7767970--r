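# Pre-processing: photobleaching correction, dF/F conversion, running-median
# detrending, and anti-aliased downsampling of electrophysiology.

# Shared time constant for the bleach model, estimated from the frame-mean
# trace by nonlinear least squares on I(t) = a * exp(-t / tau) + c. Falls
# back to Inf (flat trend) when the movie carries no decay.
estimate_bleach_tau <- function(mean_trace, frame_rate) {
  n <- length(mean_trace)
  t <- (seq_len(n) - 1L) / frame_rate
  rng <- diff(range(mean_trace))
  if (rng <= .Machine$double.eps * max(abs(mean_trace), 1)) return(Inf)
  drop0 <- mean(mean_trace[seq_len(max(2L, n %/% 10L))])
  drop1 <- mean(mean_trace[(n - max(2L, n %/% 10L) + 1L):n])
  if (drop0 <= drop1) return(Inf)           # no net decay
  tau0 <- max(t) / max(log(drop0 / max(drop1, .Machine$double.eps)), 0.1)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ a * exp(-t / tau) + c,
                 data = list(y = mean_trace, t = t),
                 start = list(a = drop0 - drop1, tau = tau0, c = drop1),
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(tau0)
  tau <- stats::coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0) tau0 else tau
}

#' Correct a movie for photobleaching
#'
#' Fits a mono-exponential-plus-offset decay and divides it out, yielding a
#' dimensionless movie with per-pixel mean ~ 1. The decay time constant is
#' estimated once from the frame-mean trace; per-pixel amplitude and offset
#' are then fitted by linear least squares on the basis
#' `{exp(-t / tau), 1}` (`method = "pixel"`, default). `method = "global"`
#' divides every pixel by the normalized frame-mean trend instead.
#' Pixels whose fitted trend is non-positive anywhere fall back to the
#' global trend (counted in attribute `n_fallback`).
#'
#' @param movie An [sto_movie()] with at least 10 frames.
#' @param method `"pixel"` or `"global"`.
#' @return Bleach-corrected [sto_movie()] (origin `"bleach-corrected"`).
#' @export
bleach_correct <- function(movie, method = c("pixel", "global")) {
  stopifnot(inherits(movie, "sto_movie"))
  method <- match.arg(method)
  d <- dim(movie$data)
  nf <- d[1L]
  if (nf < 10L) stop("bleach correction needs at least 10 frames")
  x <- matrix(movie$data, nf, d[2L] * d[3L])
  t <- (seq_len(nf) - 1L) / movie$frame_rate
  mean_trace <- rowMeans(x)
  tau <- estimate_bleach_tau(mean_trace, movie$frame_rate)
  basis <- if (is.finite(tau)) cbind(exp(-t / tau), 1) else
    matrix(1, nf, 1L)                       # flat trend: offset only
  global_trend <- {
    cf <- qr.coef(qr(basis), mean_trace)
    drop(basis %*% cf)
  }
  if (method == "global") {
    trend <- matrix(global_trend / mean(global_trend), nf, ncol(x))
    out <- x / trend
  } else {
    cf <- qr.coef(qr(basis), x)             # 2 x npix
    trend <- basis %*% cf
    bad <- apply(trend <= 0, 2L, any)
    if (any(bad)) trend[, bad] <- global_trend / mean(global_trend) *
        rep(colMeans(x[, bad, drop = FALSE]), each = nf)
    out <- x / trend
    attr(out, "n_fallback") <- sum(bad)
  }
  res <- movie
  nfb <- attr(out, "n_fallback")
  res$data <- array(out, d)
  res$origin <- "bleach-corrected"
  attr(res, "bleach_tau_s") <- tau
  attr(res, "n_fallback") <- if (is.null(nfb)) 0L else nfb
  res
}

#' Convert a movie to fractional fluorescence change
#'
#' `(F - F0) / F0` per pixel. The baseline `F0` is the per-pixel temporal
#' mean (default) or the mean over a stated pre-stimulus window.
#'
#' @param movie An [sto_movie()].
#' @param baseline `"mean"` or `c(t0, t1)` seconds (half-open window).
#' @return [sto_movie()] with origin `"dff"`. Pixels with non-positive
#'   baseline are set to `NA` with a warning rather than erroring.
#' @export
dff <- function(movie, baseline = "mean") {
  stopifnot(inherits(movie, "sto_movie"))
  d <- dim(movie$data)
  x <- matrix(movie$data, d[1L], d[2L] * d[3L])
  if (identical(baseline, "mean")) {
    f0 <- colMeans(x)
  } else {
    stopifnot(is.numeric(baseline), length(baseline) == 2L)
    t <- (seq_len(d[1L]) - 1L) / movie$frame_rate
    sel <- t >= baseline[1] & t < baseline[2]
    if (!any(sel)) stop("baseline window contains no frames")
    f0 <- colMeans(x[sel, , drop = FALSE])
  }
  bad <- !(f0 > 0)
  if (any(bad)) {
    warning(sum(bad), " pixel(s) with non-positive baseline masked as NA")
    f0[bad] <- NA_real_
  }
  out <- sweep(sweep(x, 2L, f0, "-"), 2L, f0, "/")
  res <- movie
  res$data <- array(out, d)
  res$origin <- "dff"
  res
}

#' Remove slow trends from a trace by running-median subtraction
#'
#' Subtracts a running median (default window 0.25 s) from the trace; edges
#' are handled by reflection padding. Removes baseline drift and slow
#' stimulus transients while retaining oscillations faster than ~1/window.
#'
#' @param trace Numeric vector, or an [ephys_trace()].
#' @param sample_rate Hz (ignored when `trace` is an [ephys_trace()]).
#' @param window_s Median window in seconds; must span >= 3 samples and not
#'   exceed the trace.
#' @return Detrended numeric vector (or [ephys_trace()], matching input).
#' @export
detrend_trace <- function(trace, sample_rate = NULL, window_s = 0.25) {
  is_ep <- inherits(trace, "ephys_trace")
  x <- if (is_ep) trace$samples else as.numeric(trace)
  fs <- if (is_ep) trace$sample_rate else sample_rate
  if (is.null(fs)) stop("sample_rate required for a bare numeric trace")
  k <- round(window_s * fs)
  if (k < 3L) stop("window_s x sample_rate must be at least 3 samples")
  if (k > length(x)) stop("median window longer than the trace")
  if (k %% 2L == 0L) k <- k + 1L            # runmed needs an odd window
  half <- (k - 1L) %/% 2L
  padded <- c(rev(x[seq_len(half) + 1L]), x,
              rev(x[length(x) - seq_len(half)]))
  med <- stats::runmed(padded, k, endrule = "keep")
  out <- x - med[half + seq_along(x)]
  if (is_ep) ephys_trace(out, fs) else out
}

#' Downsample an electrophysiology trace to the imaging frame rate
#'
#' Anti-aliased bin averaging: output sample `i` is the mean of the source
#' samples in the half-open window `[i, i+1) * sample_rate / target_rate`.
#' Output length is `floor(n * target_rate / sample_rate)`.
#'
#' @param trace An [ephys_trace()] or numeric vector.
#' @param target_rate Hz, at most the source rate.
#' @param sample_rate Source rate for bare numeric traces.
#' @return Numeric vector at `target_rate`.
#' @export
downsample_ephys <- function(trace, target_rate, sample_rate = NULL) {
  is_ep <- inherits(trace, "ephys_trace")
  x <- if (is_ep) trace$samples else as.numeric(trace)
  fs <- if (is_ep) trace$sample_rate else sample_rate
  if (is.null(fs)) stop("sample_rate required for a bare numeric trace")
  if (target_rate > fs)
    stop("target_rate exceeds the source sample rate; upsampling not supported")
  n_out <- floor(length(x) * target_rate / fs)
  if (n_out < 1L) stop("trace too short for the requested target rate")
  bounds <- floor((0:n_out) * fs / target_rate)
  grp <- rep.int(seq_len(n_out), diff(bounds))
  as.numeric(tapply(x[seq_len(bounds[n_out + 1L])], grp, mean))
}
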