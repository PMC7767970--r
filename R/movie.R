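# Core containers: fluorescence movie and electrophysiology trace.
#
# Coordinate convention across the package: frames are (row, col), indices
# are 0-based, ranges half-open; the time axis of movie data is axis 1 of
# the underlying R array (frames x rows x cols).

#' Construct a fluorescence movie
#'
#' @param data 3-D numeric array, frames x rows x cols, in camera counts
#'   (or dimensionless after [dff()]).
#' @param frame_rate Acquisition rate in Hz (wide-field recordings are
#'   typically 40-120 fps).
#' @param pixel_pitch Pixel size in micrometres (17.86 at 5x, 1.22 at 60x).
#' @param origin Processing state tag: `"raw"`, `"bleach-corrected"`,
#'   `"dff"` or `"detrended"`.
#' @return An object of class `sto_movie`.
#' @export
sto_movie <- function(data, frame_rate, pixel_pitch,
                      origin = c("raw", "bleach-corrected", "dff", "detrended")) {
  origin <- match.arg(origin)
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a single positive number (Hz)")
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0)
    stop("pixel_pitch must be a single positive number (um/pixel)")
  if (dim(data)[1L] < 1L) stop("movie must contain at least one frame")
  structure(list(data = data, frame_rate = frame_rate,
                 pixel_pitch = pixel_pitch, origin = origin),
            class = "sto_movie")
}

#' @export
print.sto_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sto_movie> %d frames of %d x %d px, %.6g fps, %.6g um/px [%s], %.4g s\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_pitch, x$origin,
              movie_duration(x)))
  invisible(x)
}

#' @export
dim.sto_movie <- function(x) dim(x$data)

#' Movie duration in seconds
#' @param movie An [sto_movie()].
#' @return Duration in seconds (`n_frames / frame_rate`).
#' @export
movie_duration <- function(movie) dim(movie$data)[1L] / movie$frame_rate

#' Construct an electrophysiology trace
#'
#' A membrane-voltage trace (current-clamp, typically 50 kHz) pairable with
#' an imaging recording.
#'
#' @param samples Numeric vector of membrane voltage in mV.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `ephys_trace`.
#' @export
ephys_trace <- function(samples, sample_rate) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number (Hz)")
  if (!length(samples)) stop("ephys trace must contain at least one sample")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %d samples at %.6g Hz (%.4g s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  parse_flat_config(path)
}

#' Save a movie as multi-page TIFF with a metadata sidecar
#'
#' Raw/bleach-corrected movies are stored as 16-bit unsigned pages (values
#' clamped at 0 and rounded); dimensionless dF/F and detrended movies as
#' 32-bit float pages. Frame rate, pixel pitch and origin go to a flat
#' key-value sidecar `<path>.meta`.
#'
#' @param movie An [sto_movie()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
save_movie <- function(movie, path) {
  stopifnot(inherits(movie, "sto_movie"))
  if (movie$origin %in% c("raw", "bleach-corrected")) {
    d <- round(pmax(movie$data, 0))
    if (max(d) > 65535) stop("counts exceed 16-bit range; rescale before saving")
    write_tiff(d, path, bits = 16L)
  } else {
    write_tiff(movie$data, path, bits = 32L)
  }
  writeLines(c(sprintf("frame_rate_hz: %.17g", movie$frame_rate),
               sprintf("pixel_pitch_um: %.17g", movie$pixel_pitch),
               sprintf("origin: %s", movie$origin)),
             paste0(path, ".meta"))
  invisible(path)
}

#' Load a movie from multi-page TIFF
#'
#' Metadata come from the `<path>.meta` sidecar when present; otherwise
#' `frame_rate` and `pixel_pitch` must be supplied explicitly -- there is no
#' silent default.
#'
#' @param path TIFF path.
#' @param frame_rate,pixel_pitch Override / supply metadata (Hz, um/pixel).
#' @param origin Override the stored processing-state tag.
#' @return An [sto_movie()].
#' @export
load_movie <- function(path, frame_rate = NULL, pixel_pitch = NULL,
                       origin = NULL) {
  data <- read_tiff(path)
  meta <- read_sidecar(paste0(path, ".meta"))
  frame_rate <- frame_rate %||% as_num(meta$frame_rate_hz)
  pixel_pitch <- pixel_pitch %||% as_num(meta$pixel_pitch_um)
  origin <- origin %||% meta$origin %||% "raw"
  if (is.null(frame_rate))
    stop("frame rate unknown: supply frame_rate= or a '", path,
         ".meta' sidecar with frame_rate_hz")
  if (is.null(pixel_pitch))
    stop("pixel pitch unknown: supply pixel_pitch= or a '", path,
         ".meta' sidecar with pixel_pitch_um")
  sto_movie(data, frame_rate, pixel_pitch, origin)
}

#' Crop a movie
#'
#' Ranges follow the package convention: 0-based, half-open `[from, to)`.
#'
#' @param movie An [sto_movie()].
#' @param rows,cols Integer vectors `c(from, to)`; `NULL` keeps the full
#'   extent.
#' @return The cropped [sto_movie()]; metadata unchanged.
#' @export
crop_movie <- function(movie, rows = NULL, cols = NULL) {
  stopifnot(inherits(movie, "sto_movie"))
  d <- dim(movie$data)
  rows <- rows %||% c(0L, d[2L])
  cols <- cols %||% c(0L, d[3L])
  check_range <- function(rg, n, what) {
    if (length(rg) != 2L || rg[1] < 0 || rg[2] > n || rg[1] >= rg[2])
      stop(sprintf("invalid %s range [%s, %s): must be within [0, %d) and non-empty",
                   what, rg[1], rg[2], n))
  }
  check_range(rows, d[2L], "row")
  check_range(cols, d[3L], "col")
  out <- movie
  out$data <- movie$data[, (rows[1] + 1L):rows[2], (cols[1] + 1L):cols[2],
                         drop = FALSE]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_num <- function(x) if (is.null(x)) NULL else as.numeric(x)
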