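# OPTICS (Ordering Points To Identify the Clustering Structure) on 2-D
# pixel coordinates, with xi-steepness cluster extraction from the
# reachability plot. Density-based, so clusters need not be spatially
# contiguous. Tie-breaks: points are processed in ascending (row, col)
# lexicographic order when reachabilities are equal or undefined.

#' OPTICS ordering of 2-D points
#'
#' @param coords Numeric matrix (n x 2) of point coordinates.
#' @param min_samples Neighbourhood size defining core points (the point
#'   itself counts).
#' @param max_eps Maximal neighbourhood radius; pairs farther apart are
#'   never density-reachable.
#' @return List with `order` (row indices of `coords` in processing order),
#'   `reach_plot` and `core_plot` (reachability / core distance per plot
#'   position, `Inf` when undefined).
#' @export
optics_order <- function(coords, min_samples, max_eps = Inf) {
  stopifnot(is.matrix(coords), ncol(coords) == 2L)
  n <- nrow(coords)
  if (min_samples < 2L) stop("min_samples must be at least 2")
  if (n < 1L) stop("no points to order")
  o <- order(coords[, 1L], coords[, 2L])    # lexicographic processing order
  coords <- coords[o, , drop = FALSE]

  core <- numeric(n)
  reach <- rep(Inf, n)
  processed <- logical(n)
  ordering <- integer(n)
  x <- coords[, 1L]; y <- coords[, 2L]
  dist_to <- function(i) sqrt((x - x[i])^2 + (y - y[i])^2)
  for (i in seq_len(n)) {
    d <- sort.int(dist_to(i), partial = min(min_samples, n))[min(min_samples, n)]
    core[i] <- if (n >= min_samples && d <= max_eps) d else Inf
  }
  for (k in seq_len(n)) {
    cand <- which(!processed)
    p <- cand[which.min(reach[cand])]       # ties -> lowest lexicographic
    processed[p] <- TRUE
    ordering[k] <- p
    if (is.finite(core[p])) {
      d <- dist_to(p)
      upd <- !processed & d <= max_eps
      if (any(upd)) {
        newreach <- pmax(core[p], d[upd])
        reach[upd] <- pmin(reach[upd], newreach)
      }
    }
  }
  # `order` maps plot positions back to rows of the input matrix;
  # reach_plot / core_plot are in plot (processing) order.
  list(order = o[ordering], reach_plot = reach[ordering],
       core_plot = core[ordering])
}

extend_region <- function(steep_pt, xward_pt, start, min_samples) {
  n <- length(steep_pt)
  non_xward <- 0L
  index <- start
  end <- start
  while (index <= n) {
    if (steep_pt[index]) {
      non_xward <- 0L
      end <- index
    } else if (!xward_pt[index]) {
      non_xward <- non_xward + 1L
      if (non_xward > min_samples) break
    } else return(end)
    index <- index + 1L
  }
  end
}

update_filter_sdas <- function(sdas, mib, xi_complement, rplot) {
  if (is.infinite(mib)) return(list())
  keep <- vapply(sdas, function(s) mib <= rplot[s$start] * xi_complement,
                 logical(1))
  sdas <- sdas[keep]
  lapply(sdas, function(s) { s$mib <- max(s$mib, mib); s })
}

# Extract [start, end] runs of the reachability plot that are xi-clusters.
xi_clusters <- function(rplot, xi, min_samples, min_cluster_size) {
  n <- length(rplot)
  rp <- c(rplot, Inf)
  xi_c <- 1 - xi
  ratio <- rp[seq_len(n)] / rp[seq_len(n) + 1L]
  ratio[is.nan(ratio)] <- 1                 # inf/inf: neither steep nor xward
  steep_up <- ratio <= xi_c
  steep_down <- ratio >= 1 / xi_c
  upward <- ratio < 1
  downward <- ratio > 1

  sdas <- list()
  clusters <- list()
  index <- 1L
  mib <- 0
  for (steep_index in which(steep_up | steep_down)) {
    if (steep_index < index) next
    mib <- max(mib, max(rp[index:steep_index]))
    if (steep_down[steep_index]) {
      sdas <- update_filter_sdas(sdas, mib, xi_c, rp)
      d_start <- steep_index
      d_end <- extend_region(steep_down, upward, d_start, min_samples)
      sdas[[length(sdas) + 1L]] <- list(start = d_start, end = d_end, mib = 0)
      index <- d_end + 1L
      mib <- rp[index]
    } else {
      sdas <- update_filter_sdas(sdas, mib, xi_c, rp)
      u_start <- steep_index
      u_end <- extend_region(steep_up, downward, u_start, min_samples)
      index <- u_end + 1L
      mib <- rp[index]
      u_clusters <- list()
      for (dd in sdas) {
        c_start <- dd$start
        c_end <- u_end
        if (rp[c_end + 1L] * xi_c < dd$mib) next
        d_max <- rp[dd$start]
        if (d_max * xi_c >= rp[c_end + 1L]) {
          while (c_start < dd$end && rp[c_start + 1L] > rp[c_end + 1L])
            c_start <- c_start + 1L
        } else if (rp[c_end + 1L] * xi_c >= d_max) {
          while (c_end > u_start && rp[c_end - 1L] > d_max)
            c_end <- c_end - 1L
        }
        if (c_end - c_start + 1L < min_cluster_size) next
        if (c_start > dd$end) next
        if (c_end < u_start) next
        u_clusters[[length(u_clusters) + 1L]] <- c(c_start, c_end)
      }
      clusters <- c(clusters, rev(u_clusters))
    }
  }
  clusters
}

# Labels (-1 noise, else 0-based) per ordering position; smallest
# (innermost) non-overlapping clusters win, as in standard xi extraction.
xi_labels <- function(rplot, xi, min_samples, min_cluster_size) {
  runs <- xi_clusters(rplot, xi, min_samples, min_cluster_size)
  labels <- rep(-1L, length(rplot))
  lab <- 0L
  for (rg in runs) {
    sel <- rg[1]:rg[2]
    if (all(labels[sel] == -1L)) {
      labels[sel] <- lab
      lab <- lab + 1L
    }
  }
  labels
}

# DBSCAN-equivalent extraction at a fixed eps from the OPTICS ordering.
dbscan_labels <- function(reach_plot, core_plot, eps) {
  n <- length(reach_plot)
  labels <- rep(-1L, n)
  lab <- -1L
  for (i in seq_len(n)) {
    if (reach_plot[i] > eps) {
      if (core_plot[i] <= eps) {
        lab <- lab + 1L
        labels[i] <- lab
      }
    } else labels[i] <- lab
  }
  labels
}
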