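# Staining quantification: mesoscale radial spread around the injection
# centre, half-maximal radius, per-cell radial profiles with subcellular
# compartment statistics, and membrane-labeling homogeneity.

#' Subcellular compartment bounds
#'
#' Radial limits (um from the cell centre) separating nucleus, cytosol and
#' neuropil: nucleus 0-3.5 um, cytosol 3.5-10 um, neuropil beyond 10 um.
#'
#' @param nucleus_um,soma_um Outer radii of nucleus and soma.
#' @return A named list with `nucleus`, `cytosol`, `neuropil` interval
#'   vectors.
#' @export
compartment_bounds <- function(nucleus_um = 3.5, soma_um = 10) {
  if (nucleus_um <= 0 || soma_um <= nucleus_um)
    stop("require 0 < nucleus_um < soma_um")
  list(nucleus = c(0, nucleus_um), cytosol = c(nucleus_um, soma_um),
       neuropil = c(soma_um, Inf))
}

#' Estimate the injection centre of a staining image
#'
#' Centroid of the brightest pixels (default top 0.1%), in micrometres.
#'
#' @param image Numeric matrix with a `pixel_pitch` attribute, or supply
#'   `pixel_pitch`.
#' @param top_fraction Fraction of brightest pixels averaged.
#' @param pixel_pitch um/pixel.
#' @return `c(row, col)` in micrometres.
#' @export
injection_center <- function(image, top_fraction = 0.001,
                             pixel_pitch = attr(image, "pixel_pitch")) {
  if (is.null(pixel_pitch)) stop("pixel_pitch unknown")
  thr <- stats::quantile(image, 1 - top_fraction, names = FALSE)
  sel <- which(image >= thr)
  c(mean(row(image)[sel] - 1L), mean(col(image)[sel] - 1L)) * pixel_pitch
}

#' Azimuthally averaged radial intensity profile
#'
#' Mean intensity per annulus `[r, r + bin)` around a centre; annulus
#' membership by pixel-centre distance. Empty annuli are `NA`, not zero.
#'
#' @param image Numeric matrix.
#' @param center `c(row, col)` in micrometres.
#' @param r_max_um Outer radius, um.
#' @param bin_width_um Bin width, um; default one pixel pitch.
#' @param pixel_pitch um/pixel (default from the image attribute).
#' @return A `radial_profile` list: `radii_um` (bin centres),
#'   `intensity`, `center`, `normalization`.
#' @export
radial_profile <- function(image, center, r_max_um, bin_width_um = NULL,
                           pixel_pitch = attr(image, "pixel_pitch")) {
  stopifnot(is.matrix(image))
  if (is.null(pixel_pitch)) stop("pixel_pitch unknown")
  bin_width_um <- bin_width_um %||% pixel_pitch
  if (r_max_um <= bin_width_um) stop("r_max_um must exceed bin_width_um")
  if (center[1] < 0 || center[1] > (nrow(image) - 1) * pixel_pitch ||
      center[2] < 0 || center[2] > (ncol(image) - 1) * pixel_pitch)
    stop("center outside the image")
  r <- sqrt(((row(image) - 1L) * pixel_pitch - center[1])^2 +
              ((col(image) - 1L) * pixel_pitch - center[2])^2)
  nb <- ceiling(r_max_um / bin_width_um)
  bin <- findInterval(r, (0:nb) * bin_width_um, rightmost.closed = FALSE)
  keep <- bin >= 1L & bin <= nb & r < r_max_um
  sums <- tapply(image[keep], bin[keep], mean)
  intensity <- rep(NA_real_, nb)
  intensity[as.integer(names(sums))] <- as.numeric(sums)
  structure(list(radii_um = ((seq_len(nb)) - 0.5) * bin_width_um,
                 intensity = intensity, center = center,
                 bin_width_um = bin_width_um, normalization = "raw"),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d bins of %g um around (%.1f, %.1f) um [%s]\n",
              length(x$radii_um), x$bin_width_um, x$center[1], x$center[2],
              x$normalization))
  invisible(x)
}

#' Half-maximal radius of a radial profile
#'
#' Smallest radius beyond the profile peak at which intensity first falls
#' below `(peak + baseline) / 2`, linearly interpolated between bins. The
#' baseline is the mean of the outermost 10% of bins. A profile that never
#' falls below half-max within its extent is censored at the outermost
#' radius.
#'
#' @param profile A `radial_profile`.
#' @return Radius in um, with attribute `censored` (`TRUE` when no
#'   half-crossing exists; the value is then the outermost bin radius).
#' @export
half_max_radius <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  y <- profile$intensity
  r <- profile$radii_um
  ok <- is.finite(y)
  y <- y[ok]; r <- r[ok]
  if (!length(y) || max(y) <= 0) stop("profile has no positive peak")
  n_base <- max(1L, ceiling(length(y) * 0.1))
  baseline <- mean(y[(length(y) - n_base + 1L):length(y)])
  peak_i <- which.max(y)
  half <- (y[peak_i] + baseline) / 2
  below <- which(y < half & seq_along(y) > peak_i)
  if (!length(below)) {
    out <- r[length(r)]
    attr(out, "censored") <- TRUE
    return(out)
  }
  j <- below[1L]
  out <- r[j - 1L] + (y[j - 1L] - half) / (y[j - 1L] - y[j]) * (r[j] - r[j - 1L])
  attr(out, "censored") <- FALSE
  out
}

#' Per-cell radial profiles with angular segmentation
#'
#' Radial intensity profile on a disc (default 20 um) around a cell centre:
#' the 360-degree average plus `n_segments` angular-segment profiles
#' (default 18 segments of 20 degrees, starting at the image row axis,
#' counterclockwise). All profiles are min-max normalized using the range
#' of the averaged profile, so the averaged profile peaks at exactly 1 and
#' segment profiles stay mutually comparable.
#'
#' @param image Numeric matrix.
#' @param cell_center `c(row, col)` in micrometres; the disc must fit
#'   inside the image.
#' @param radius_um Disc radius (default 20 um).
#' @param n_segments Number of angular segments.
#' @param bin_width_um Radial bin width; default one pixel pitch.
#' @param pixel_pitch um/pixel.
#' @param normalize Min-max normalize (default TRUE).
#' @return List with `average` (a `radial_profile`) and `segments` (matrix
#'   bins x segments), plus `radii_um` and `segment_centers_deg`.
#' @export
cell_radial_profile <- function(image, cell_center, radius_um = 20,
                                n_segments = 18L, bin_width_um = NULL,
                                pixel_pitch = attr(image, "pixel_pitch"),
                                normalize = TRUE) {
  stopifnot(is.matrix(image))
  if (is.null(pixel_pitch)) stop("pixel_pitch unknown")
  bin_width_um <- bin_width_um %||% pixel_pitch
  lim_r <- (nrow(image) - 1) * pixel_pitch
  lim_c <- (ncol(image) - 1) * pixel_pitch
  if (cell_center[1] - radius_um < 0 || cell_center[1] + radius_um > lim_r ||
      cell_center[2] - radius_um < 0 || cell_center[2] + radius_um > lim_c)
    stop("cell disc clipped by the image border")
  dr <- (row(image) - 1L) * pixel_pitch - cell_center[1]
  dc <- (col(image) - 1L) * pixel_pitch - cell_center[2]
  r <- sqrt(dr^2 + dc^2)
  keep <- r < radius_um
  theta <- atan2(dc[keep], dr[keep]) %% (2 * pi)   # 0 = row axis, ccw
  seg <- pmin(floor(theta / (2 * pi / n_segments)) + 1L, n_segments)
  nb <- ceiling(radius_um / bin_width_um)
  bin <- pmin(floor(r[keep] / bin_width_um) + 1L, nb)
  vals <- image[keep]
  avg <- tapply(vals, bin, mean)
  average <- rep(NA_real_, nb)
  average[as.integer(names(avg))] <- as.numeric(avg)
  segments <- matrix(NA_real_, nb, n_segments)
  sums <- tapply(vals, list(bin, seg), mean)
  segments[cbind(as.integer(rep(rownames(sums), ncol(sums))),
                 as.integer(rep(colnames(sums), each = nrow(sums))))] <-
    as.numeric(sums)
  if (normalize) {
    lo <- min(average, na.rm = TRUE); hi <- max(average, na.rm = TRUE)
    if (hi > lo) {
      average <- (average - lo) / (hi - lo)
      segments <- (segments - lo) / (hi - lo)
    }
  }
  radii <- (seq_len(nb) - 0.5) * bin_width_um
  avg_prof <- structure(list(radii_um = radii, intensity = average,
                             center = cell_center,
                             bin_width_um = bin_width_um,
                             normalization = if (normalize) "min-max" else "raw"),
                        class = "radial_profile")
  list(average = avg_prof, segments = segments, radii_um = radii,
       segment_centers_deg = (seq_len(n_segments) - 0.5) * 360 / n_segments)
}

#' Compartment statistics from per-cell radial profiles
#'
#' Mean intensity per subcellular compartment, the cytosol-to-neuropil
#' ratio, the peak-intensity radius, and the fraction of cells carrying
#' more than half of their (cytosol + neuropil) signal in the cytosol.
#'
#' @param profiles A single result of [cell_radial_profile()] or a list of
#'   them (one per cell).
#' @param bounds A [compartment_bounds()] list.
#' @return List with `per_cell` (data frame: `nucleus`, `cytosol`,
#'   `neuropil`, `cytosol_neuropil_ratio`, `peak_radius_um`,
#'   `cytosol_dominant`) and `fraction_cytosol_dominant`.
#' @export
compartment_stats <- function(profiles, bounds = compartment_bounds()) {
  if (!is.null(profiles$average)) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    r <- p$average$radii_um
    y <- p$average$intensity
    if (max(r) <= bounds$cytosol[2])
      stop("profiles must extend beyond the soma radius (", bounds$cytosol[2],
           " um)")
    seg_mean <- function(b) mean(y[r >= b[1] & r < b[2]], na.rm = TRUE)
    nuc <- seg_mean(bounds$nucleus)
    cyt <- seg_mean(bounds$cytosol)
    np <- seg_mean(bounds$neuropil)
    data.frame(nucleus = nuc, cytosol = cyt, neuropil = np,
               cytosol_neuropil_ratio = cyt / np,
               peak_radius_um = r[which.max(y)],
               cytosol_dominant = cyt / (cyt + np) > 0.5)
  })
  per_cell <- do.call(rbind, rows)
  list(per_cell = per_cell,
       fraction_cytosol_dominant = mean(per_cell$cytosol_dominant))
}

#' Across-segment variability of peak labeling
#'
#' Standard deviation across angular segments of the per-segment peak
#' intensity (profiles are normalized upstream): 0 for a rotationally
#' symmetric cell, larger when labeling is punctate.
#'
#' @param profiles A result of [cell_radial_profile()] (its `segments`
#'   matrix) or such a matrix directly.
#' @return Standard deviation of segment peak intensities.
#' @export
segment_variability <- function(profiles) {
  seg <- if (is.matrix(profiles)) profiles else profiles$segments
  if (is.null(seg) || ncol(seg) < 2L) stop("need at least 2 segments")
  peaks <- apply(seg, 2L, max, na.rm = TRUE)
  stats::sd(peaks)
}
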