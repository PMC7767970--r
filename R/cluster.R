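# Grouping thresholded PSD pixels into clusters of synchronously
# oscillating pixels, with the minimum cluster size grounded in neuron
# morphology.

#' Pixels covered by one neuron footprint
#'
#' Number of pixels needed to contain a (circular) neuron footprint:
#' `round(pi * (diameter/2)^2 / pitch^2)`, at least 1. With the 110 um
#' dendritic-ellipse diameter and the 18 um pixel of a 5x objective this
#' gives 29 pixels.
#'
#' @param diameter_um Footprint diameter, um.
#' @param pixel_pitch_um Pixel size, um.
#' @return Integer pixel count (>= 1).
#' @export
neuron_footprint_pixels <- function(diameter_um, pixel_pitch_um) {
  if (!is.numeric(diameter_um) || diameter_um <= 0 ||
      !is.numeric(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("diameter_um and pixel_pitch_um must be positive")
  max(1L, as.integer(round(pi * (diameter_um / 2)^2 / pixel_pitch_um^2)))
}

#' Minimum cluster size from morphology
#'
#' The working minimum ("a significant portion of one neuron") is a
#' fraction of the per-neuron pixel count; the default fraction 5/29
#' reproduces the 5-pixel minimum at 5x geometry.
#'
#' @param diameter_um,pixel_pitch_um As in [neuron_footprint_pixels()].
#' @param fraction Significant-portion fraction.
#' @return Integer minimum cluster size (>= 1).
#' @export
min_cluster_size_from_morphology <- function(diameter_um = 110,
                                             pixel_pitch_um = 18,
                                             fraction = 5 / 29) {
  max(1L, as.integer(round(
    neuron_footprint_pixels(diameter_um, pixel_pitch_um) * fraction)))
}

#' Cluster masked PSD pixels with OPTICS
#'
#' Runs OPTICS over the (row, col) coordinates of the masked-in pixels of a
#' thresholded PSD image and extracts clusters (default: xi-steepness
#' extraction, xi = 0.05). Every reported cluster has at least
#' `min_cluster_size` members; clusters are sorted by descending mean band
#' power and given ids from 0. Unclustered pixels are labelled -1.
#'
#' @param img A `psd_image` carrying a mask (see [threshold_quantile()]).
#' @param min_cluster_size Minimal pixels per cluster (default 5).
#' @param max_eps Maximal reachability distance in pixels (default 5).
#' @param xi Steepness threshold for cluster extraction.
#' @param min_samples Core-point neighbourhood size; defaults to
#'   `min_cluster_size`.
#' @param method `"xi"` (default) or `"dbscan"` (flat extraction at
#'   reachability `max_eps`).
#' @return A `pixel_cluster_set`: `labels` (frame-sized integer matrix, -1 =
#'   noise), `clusters` (list of per-cluster records: `id`, `pixels`
#'   (0-based (row, col) matrix), `centroid`, `size`, `mean_band_power`)
#'   and `params`.
#' @export
cluster_pixels <- function(img, min_cluster_size = 5L, max_eps = 5,
                           xi = 0.05, min_samples = min_cluster_size,
                           method = c("xi", "dbscan")) {
  stopifnot(inherits(img, "psd_image"))
  method <- match.arg(method)
  if (is.null(img$mask))
    stop("PSD image carries no mask; run threshold_quantile()/zscore_filter() first")
  labels <- matrix(-1L, nrow(img$band_power), ncol(img$band_power))
  sel <- which(img$mask)
  empty <- structure(list(labels = labels, clusters = list(),
                          params = list(min_cluster_size = min_cluster_size,
                                        max_eps = max_eps, xi = xi,
                                        min_samples = min_samples,
                                        method = method),
                          pixel_pitch = img$pixel_pitch),
                     class = "pixel_cluster_set")
  if (length(sel) < min_cluster_size) {
    message("fewer masked pixels (", length(sel), ") than min_cluster_size (",
            min_cluster_size, "): empty cluster set")
    return(empty)
  }
  coords <- cbind(row(img$band_power)[sel] - 1L, col(img$band_power)[sel] - 1L)
  res <- optics_order(coords, min_samples = max(2L, min_samples),
                      max_eps = max_eps)
  lab_plot <- if (method == "xi") {
    xi_labels(res$reach_plot, xi, max(2L, min_samples), min_cluster_size)
  } else {
    dbscan_labels(res$reach_plot, res$core_plot, max_eps)
  }
  lab <- integer(nrow(coords))
  lab[res$order] <- lab_plot
  # enforce minimum size (dbscan path may yield smaller runs)
  keep_ids <- as.integer(names(which(table(lab[lab >= 0]) >= min_cluster_size)))
  clusters <- list()
  for (cid in keep_ids) {
    members <- which(lab == cid)
    px <- coords[members, , drop = FALSE]
    bp <- img$band_power[cbind(px[, 1] + 1L, px[, 2] + 1L)]
    clusters[[length(clusters) + 1L]] <- list(
      pixels = px, centroid = colMeans(px), size = nrow(px),
      mean_band_power = mean(bp))
  }
  if (!length(clusters)) return(empty)
  ord <- order(vapply(clusters, `[[`, numeric(1), "mean_band_power"),
               decreasing = TRUE)
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$id <- i - 1L
    px <- clusters[[i]]$pixels
    labels[cbind(px[, 1] + 1L, px[, 2] + 1L)] <- i - 1L
  }
  structure(list(labels = labels, clusters = clusters,
                 params = list(min_cluster_size = min_cluster_size,
                               max_eps = max_eps, xi = xi,
                               min_samples = min_samples, method = method),
                 pixel_pitch = img$pixel_pitch),
            class = "pixel_cluster_set")
}

#' @export
print.pixel_cluster_set <- function(x, ...) {
  cat(sprintf("<pixel_cluster_set> %d cluster(s), %d pixel(s) clustered, %d noise\n",
              length(x$clusters),
              sum(x$labels >= 0), sum(x$labels == -1L & !is.na(x$labels))))
  for (cl in x$clusters)
    cat(sprintf("  #%d: %d px, centroid (%.1f, %.1f), mean band power %.3g\n",
                cl$id, cl$size, cl$centroid[1], cl$centroid[2],
                cl$mean_band_power))
  invisible(x)
}

#' Average dF/F trace of a cluster
#'
#' Unweighted per-frame mean over the cluster's member pixels; raw movies
#' are converted to dF/F first.
#'
#' @param movie An [sto_movie()].
#' @param cluster One element of a `pixel_cluster_set`'s `clusters` list
#'   (or any list with a 0-based `pixels` matrix).
#' @return Numeric trace, one value per frame.
#' @export
cluster_trace <- function(movie, cluster) {
  stopifnot(inherits(movie, "sto_movie"))
  px <- cluster$pixels
  if (is.null(px) || nrow(px) == 0L) stop("empty cluster")
  d <- dim(movie$data)
  if (any(px[, 1] < 0 | px[, 1] >= d[2L] | px[, 2] < 0 | px[, 2] >= d[3L]))
    stop("cluster pixels outside the frame")
  if (movie$origin %in% c("raw", "bleach-corrected"))
    movie <- suppressWarnings(dff(movie))
  x <- matrix(movie$data, d[1L], d[2L] * d[3L])
  idx <- px[, 1] + 1L + px[, 2] * d[2L]
  rowMeans(x[, idx, drop = FALSE])
}

#' Cluster geometry table
#'
#' @param cluster_set A `pixel_cluster_set`.
#' @param reference_point Pixel coordinates `c(row, col)` (0-based) of the
#'   reference (e.g. injection centre).
#' @param pixel_pitch um per pixel; defaults to the set's stored pitch.
#' @return Data frame per cluster: centroid distance to the reference (um),
#'   mean pairwise inter-pixel distance (um), area (um^2).
#' @export
cluster_geometry <- function(cluster_set, reference_point,
                             pixel_pitch = NULL) {
  stopifnot(inherits(cluster_set, "pixel_cluster_set"))
  pitch <- pixel_pitch %||% cluster_set$pixel_pitch
  if (is.null(pitch) || pitch <= 0) stop("pixel pitch unknown")
  rows <- lapply(cluster_set$clusters, function(cl) {
    px <- cl$pixels
    mpd <- if (nrow(px) > 1L) mean(stats::dist(px)) * pitch else 0
    data.frame(id = cl$id, n_pixels = cl$size,
               centroid_row = cl$centroid[1], centroid_col = cl$centroid[2],
               centroid_dist_um = sqrt(sum((cl$centroid - reference_point)^2)) * pitch,
               mean_pairwise_um = mpd,
               area_um2 = cl$size * pitch^2,
               mean_band_power = cl$mean_band_power)
  })
  if (!length(rows))
    return(data.frame(id = integer(), n_pixels = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      centroid_dist_um = numeric(),
                      mean_pairwise_um = numeric(), area_um2 = numeric(),
                      mean_band_power = numeric()))
  do.call(rbind, rows)
}
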