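# Ground-truth generators. The generative model mirrors the imaging
# physiology being analysed: spatial clusters of neurons expressing
# sinusoidal subthreshold oscillations (3-12 Hz, a few mV), read out by an
# electrochromic dye whose fluorescence gains 0.5% dF/F per mV of
# depolarization, on top of a photobleaching decay and sensor noise.

#' Specify one synchronously oscillating cluster
#'
#' @param center Pixel coordinates `c(row, col)` of the cluster centre
#'   (0-based).
#' @param frequency_hz Oscillation frequency in Hz. Subthreshold
#'   oscillations live in the 3-12 Hz band; frequencies outside it are
#'   rejected unless `check_band = FALSE`.
#' @param amplitude_mv Peak-to-peak amplitude in mV (typically 2-10 mV).
#' @param footprint_diameter_um Diameter of the (circular) cluster footprint
#'   in micrometres; default 110 um, the short diameter of an inferior olive
#'   neuron's dendritic ellipse.
#' @param phase_rad Oscillation phase in radians at t = 0.
#' @param onset_s,offset_s Active time window in seconds.
#' @param check_band If `FALSE`, allow frequencies outside 3-12 Hz.
#' @return A `cluster_spec` list.
#' @export
cluster_spec <- function(center, frequency_hz, amplitude_mv,
                         footprint_diameter_um = 110, phase_rad = 0,
                         onset_s = 0, offset_s = Inf, check_band = TRUE) {
  stopifnot(length(center) == 2L, is.numeric(center))
  if (check_band && (frequency_hz < 3 || frequency_hz > 12))
    stop("frequency_hz outside the 3-12 Hz subthreshold band; ",
         "pass check_band = FALSE to override")
  if (frequency_hz <= 0) stop("frequency_hz must be positive")
  if (amplitude_mv < 0) stop("amplitude_mv must be >= 0")
  if (footprint_diameter_um <= 0) stop("footprint_diameter_um must be positive")
  if (offset_s <= onset_s) stop("offset_s must exceed onset_s")
  structure(list(center = as.numeric(center),
                 footprint_diameter_um = footprint_diameter_um,
                 frequency_hz = frequency_hz, amplitude_mv = amplitude_mv,
                 phase_rad = phase_rad, onset_s = onset_s,
                 offset_s = offset_s),
            class = "cluster_spec")
}

#' Specify an afferent stimulation train
#'
#' Emulates extracellular stimulation of excitatory afferents: a short pulse
#' train (default 10 pulses at 10 Hz) that entrains all clusters to a common
#' frequency afterwards, with per-cluster phase and amplitude gain, and a
#' brief negative deflection artifact at each pulse.
#'
#' @param onset_s Train onset, seconds.
#' @param n_pulses Number of pulses (default 10).
#' @param pulse_rate_hz Pulse rate in Hz (default 10).
#' @param entrained_frequency_hz Common post-train oscillation frequency.
#' @param power_gain Multiplicative factor on post-train amplitude.
#' @param post_phase_rad Per-cluster post-train phase (recycled).
#' @param artifact_mv Peak size of the negative pulse artifact, mV.
#' @return A `stim_spec` list.
#' @export
stim_spec <- function(onset_s, n_pulses = 10L, pulse_rate_hz = 10,
                      entrained_frequency_hz, power_gain = 1,
                      post_phase_rad = 0, artifact_mv = 5) {
  if (onset_s < 0 || n_pulses < 1L || pulse_rate_hz <= 0)
    stop("invalid stimulation train parameters")
  if (entrained_frequency_hz <= 0) stop("entrained_frequency_hz must be positive")
  if (power_gain < 0) stop("power_gain must be >= 0")
  structure(list(onset_s = onset_s, n_pulses = as.integer(n_pulses),
                 pulse_rate_hz = pulse_rate_hz,
                 entrained_frequency_hz = entrained_frequency_hz,
                 power_gain = power_gain, post_phase_rad = post_phase_rad,
                 artifact_mv = artifact_mv),
            class = "stim_spec")
}

#' Scene configuration for the movie generator
#'
#' Defaults state the recording conditions of the emulated experiments:
#' 256 x 256 px at 17.86 um/px (5x objective), 40-120 fps, dye sensitivity
#' 0.005 dF/F per mV, 10 s duration.
#'
#' @param frame_size `c(rows, cols)` in pixels.
#' @param frame_rate Frames per second; must exceed twice the fastest
#'   cluster frequency.
#' @param pixel_pitch um per pixel.
#' @param duration_s Recording length, seconds.
#' @param clusters List of [cluster_spec()] objects.
#' @param sensitivity Fractional dF/F per mV (0.005 for the dye emulated).
#' @param baseline_intensity Resting fluorescence, counts.
#' @param bleach_tau_s Mono-exponential photobleaching time constant,
#'   seconds (`Inf` disables bleaching). Default 100 s: ~10% decay over a
#'   10 s trial.
#' @param noise_sd Additive Gaussian sensor noise, counts per pixel-frame.
#'   Default 5 counts = 0.5% of the default baseline.
#' @param noise_model `"gaussian"` (default) or `"poisson"` (shot noise on
#'   the noiseless signal; `noise_sd` then ignored).
#' @param stim Optional [stim_spec()].
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @return A `scene_config` list.
#' @export
scene_config <- function(frame_size = c(256L, 256L), frame_rate = 120,
                         pixel_pitch = 17.86, duration_s = 10,
                         clusters = list(), sensitivity = 0.005,
                         baseline_intensity = 1000, bleach_tau_s = 100,
                         noise_sd = 5, noise_model = c("gaussian", "poisson"),
                         stim = NULL, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(frame_size) == 2L, all(frame_size >= 1))
  if (frame_rate <= 0 || pixel_pitch <= 0 || duration_s <= 0 ||
      sensitivity <= 0 || baseline_intensity <= 0 || bleach_tau_s <= 0 ||
      noise_sd < 0)
    stop("all physical scene parameters must be positive (noise_sd >= 0)")
  if (length(clusters) && inherits(clusters, "cluster_spec"))
    clusters <- list(clusters)
  for (cl in clusters) stopifnot(inherits(cl, "cluster_spec"))
  if (!is.null(stim)) {
    stopifnot(inherits(stim, "stim_spec"))
    if (stim$onset_s + stim$n_pulses / stim$pulse_rate_hz >= duration_s)
      stop("stimulation train must end before the recording does")
  }
  structure(list(frame_size = as.integer(frame_size), frame_rate = frame_rate,
                 pixel_pitch = pixel_pitch, duration_s = duration_s,
                 clusters = clusters, sensitivity = sensitivity,
                 baseline_intensity = baseline_intensity,
                 bleach_tau_s = bleach_tau_s, noise_sd = noise_sd,
                 noise_model = noise_model, stim = stim,
                 seed = as.integer(seed)),
            class = "scene_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

footprint_pixels_idx <- function(center, diameter_um, pitch, frame_size) {
  r_px <- (diameter_um / 2) / pitch
  if (center[1] - r_px < -0.5 || center[1] + r_px > frame_size[1] - 0.5 ||
      center[2] - r_px < -0.5 || center[2] + r_px > frame_size[2] - 0.5)
    stop("cluster footprint extends outside the frame")
  rows <- 0:(frame_size[1] - 1L); cols <- 0:(frame_size[2] - 1L)
  dr <- outer(rows - center[1], rep(1, frame_size[2]))
  dc <- outer(rep(1, frame_size[1]), cols - center[2])
  which(dr^2 + dc^2 <= r_px^2)              # column-major indices into a frame
}

# Per-cluster voltage time course in mV, honouring onset/offset and any
# stimulation train (entrainment + pulse artifacts).
cluster_voltage <- function(cl, t, stim) {
  amp <- cl$amplitude_mv / 2                # peak-to-peak -> amplitude
  v <- numeric(length(t))
  active <- t >= cl$onset_s & t < cl$offset_s
  if (is.null(stim)) {
    v[active] <- amp * sin(2 * pi * cl$frequency_hz * t[active] + cl$phase_rad)
    return(v)
  }
  train_end <- stim$onset_s + stim$n_pulses / stim$pulse_rate_hz
  pre <- active & t < train_end
  post <- active & t >= train_end
  v[pre] <- amp * sin(2 * pi * cl$frequency_hz * t[pre] + cl$phase_rad)
  v[post] <- amp * stim$power_gain *
    sin(2 * pi * stim$entrained_frequency_hz * (t[post] - train_end) +
          cl$post_phase_rad)
  pulse_times <- stim$onset_s + (seq_len(stim$n_pulses) - 1L) / stim$pulse_rate_hz
  dt <- t[2] - t[1]
  for (pt in pulse_times) {
    k <- which.min(abs(t - pt))
    if (abs(t[k] - pt) <= dt) v[k] <- v[k] - stim$artifact_mv
  }
  v
}

#' Generate a ground-truth subthreshold-oscillation movie
#'
#' Renders each pixel as
#' `baseline * exp(-t / bleach_tau) * (1 + sensitivity * V(t)) + noise`,
#' where `V(t)` (mV) is the superposition of the oscillations of all
#' clusters covering the pixel; depolarization increases fluorescence.
#'
#' @param config A [scene_config()].
#' @return A `movie_fixture` list: `movie` (an [sto_movie()]), `labels`
#'   (integer ground-truth map, cluster ids from 0, -1 = background),
#'   `clusters` (per-cluster parameter table) and `config`.
#' @export
generate_sto_movie <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  freqs <- vapply(config$clusters, `[[`, numeric(1), "frequency_hz")
  if (length(freqs)) {
    fmax <- max(freqs, if (!is.null(config$stim))
      config$stim$entrained_frequency_hz else -Inf)
    if (config$frame_rate <= 2 * fmax)
      stop(sprintf(paste0("frame rate %.6g Hz violates the Nyquist limit for a ",
                          "%.6g Hz oscillation (need > %.6g Hz)"),
                   config$frame_rate, fmax, 2 * fmax))
  }
  nf <- round(config$duration_s * config$frame_rate)
  t <- (seq_len(nf) - 1L) / config$frame_rate
  fs <- config$frame_size
  npx <- prod(fs)

  labels <- matrix(-1L, fs[1], fs[2])
  vmat <- matrix(0, nf, npx)                # summed mV per pixel
  stim <- config$stim
  clusters <- config$clusters
  i <- 0L
  post_phase <- if (!is.null(stim))
    rep_len(stim$post_phase_rad, length(clusters)) else NULL
  rows_tab <- vector("list", length(clusters))
  for (cl in clusters) {
    i <- i + 1L
    idx <- footprint_pixels_idx(cl$center, cl$footprint_diameter_um,
                                config$pixel_pitch, fs)
    cl$post_phase_rad <- if (!is.null(stim)) post_phase[i] else NA_real_
    v <- cluster_voltage(cl, t, stim)
    vmat[, idx] <- vmat[, idx] + v
    unclaimed <- idx[labels[idx] == -1L]
    labels[unclaimed] <- i - 1L             # first cluster claims the pixel
    rows_tab[[i]] <- data.frame(
      id = i - 1L, center_row = cl$center[1], center_col = cl$center[2],
      footprint_diameter_um = cl$footprint_diameter_um,
      frequency_hz = cl$frequency_hz, amplitude_mv = cl$amplitude_mv,
      phase_rad = cl$phase_rad, onset_s = cl$onset_s, offset_s = cl$offset_s,
      post_phase_rad = cl$post_phase_rad, n_pixels = length(unclaimed))
  }
  bleach <- if (is.finite(config$bleach_tau_s))
    exp(-t / config$bleach_tau_s) else rep(1, nf)
  signal <- config$baseline_intensity * bleach *
    (1 + config$sensitivity * vmat)         # bleach recycles down columns
  data <- with_seed(config$seed, {
    if (config$noise_model == "poisson") {
      matrix(stats::rpois(nf * npx, lambda = pmax(signal, 0)), nf, npx)
    } else if (config$noise_sd > 0) {
      signal + matrix(stats::rnorm(nf * npx, sd = config$noise_sd), nf, npx)
    } else signal
  })
  movie <- sto_movie(array(data, c(nf, fs[1], fs[2])),
                     config$frame_rate, config$pixel_pitch, "raw")
  cluster_table <- if (length(rows_tab)) do.call(rbind, rows_tab) else
    data.frame(id = integer(), center_row = numeric(), center_col = numeric(),
               footprint_diameter_um = numeric(), frequency_hz = numeric(),
               amplitude_mv = numeric(), phase_rad = numeric(),
               onset_s = numeric(), offset_s = numeric(),
               post_phase_rad = numeric(), n_pixels = integer())
  structure(list(movie = movie, labels = labels, clusters = cluster_table,
                 config = config),
            class = "movie_fixture")
}

#' Generate a paired current-clamp trace for a cluster
#'
#' Returns a membrane-voltage trace (mV) sharing the cluster's frequency and
#' phase, sampled at electrophysiology rates (default 50 kHz), so that the
#' imaging/electrophysiology comparison operators can be exercised on ground
#' truth.
#'
#' @param cluster A [cluster_spec()].
#' @param sample_rate Hz; must be at least twice the cluster frequency.
#' @param duration_s Trace length in seconds.
#' @param noise_sd_mv Additive Gaussian noise, mV.
#' @param seed RNG seed used when `noise_sd_mv > 0`.
#' @return An [ephys_trace()].
#' @export
generate_paired_ephys <- function(cluster, sample_rate = 50000,
                                  duration_s = 10, noise_sd_mv = 0,
                                  seed = 1L) {
  stopifnot(inherits(cluster, "cluster_spec"))
  if (duration_s <= 0) stop("duration_s must be positive: empty trace requested")
  if (sample_rate < 2 * cluster$frequency_hz)
    stop("sample_rate below twice the cluster frequency")
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  v <- numeric(n)
  active <- t >= cluster$onset_s & t < cluster$offset_s
  v[active] <- cluster$amplitude_mv / 2 *
    sin(2 * pi * cluster$frequency_hz * t[active] + cluster$phase_rad)
  if (noise_sd_mv > 0)
    v <- v + with_seed(seed, stats::rnorm(n, sd = noise_sd_mv))
  ephys_trace(v, sample_rate)
}

#' Specify a synthetic staining field
#'
#' Describes a dye-injection scene: a radially decaying mesoscale intensity
#' field around the injection centre plus individually rendered cells with
#' nucleus / cytosol / neuropil compartment contrast (and optional membrane
#' ring and fluorescent puncta).
#'
#' @param frame_size `c(rows, cols)`, pixels.
#' @param pixel_pitch um per pixel (confocal scale, e.g. 0.44).
#' @param injection_center `c(row, col)` in micrometres; default frame
#'   centre.
#' @param profile_shape `"gaussian"` or `"gaussian-with-tail"` (adds a slow
#'   exponential tail, as dye profiles acquire days after injection).
#' @param half_max_radius_um Radius at which the azimuthal mean falls to
#'   half its peak.
#' @param peak_intensity Peak counts at the injection centre.
#' @param tail_fraction,tail_scale_um Tail amplitude (fraction of peak) and
#'   length scale for `"gaussian-with-tail"`.
#' @param cells List of cell descriptions; see [staining_cell()].
#' @param noise_sd Additive Gaussian noise, counts.
#' @param seed RNG seed.
#' @return A `staining_field_spec` list.
#' @export
staining_field_spec <- function(frame_size = c(256L, 256L), pixel_pitch = 1,
                                injection_center = NULL,
                                profile_shape = c("gaussian", "gaussian-with-tail"),
                                half_max_radius_um = 100,
                                peak_intensity = 1000,
                                tail_fraction = 0.2, tail_scale_um = 150,
                                cells = list(), noise_sd = 0, seed = 1L) {
  profile_shape <- match.arg(profile_shape)
  if (half_max_radius_um <= 0) stop("half_max_radius_um must be positive")
  if (peak_intensity < 0) stop("peak_intensity must be >= 0")
  injection_center <- injection_center %||%
    ((as.numeric(frame_size) - 1) / 2 * pixel_pitch)
  for (cl in cells) stopifnot(inherits(cl, "staining_cell"))
  structure(list(frame_size = as.integer(frame_size),
                 pixel_pitch = pixel_pitch,
                 injection_center = injection_center,
                 profile_shape = profile_shape,
                 half_max_radius_um = half_max_radius_um,
                 peak_intensity = peak_intensity,
                 tail_fraction = tail_fraction, tail_scale_um = tail_scale_um,
                 cells = cells, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "staining_field_spec")
}

#' Describe one rendered cell in a staining field
#'
#' Compartment intensities are additive contributions (fraction of the
#' field's `peak_intensity`) within the cell's rendering disc: nucleus
#' `[0, nucleus_radius)`, cytosol `[nucleus_radius, soma_radius)`, neuropil
#' `[soma_radius, render_radius)`. An optional Gaussian membrane ring at the
#' soma radius and randomly placed cytosolic puncta emulate the subcellular
#' structure seen at high magnification.
#'
#' @param center `c(row, col)` in micrometres.
#' @param nucleus_radius_um,soma_radius_um Compartment radii (defaults 3.5
#'   and 10 um); the nucleus must be smaller than the soma.
#' @param nucleus_ratio,cytosol_ratio,neuropil_ratio Compartment intensity
#'   ratios (x `peak_intensity`).
#' @param membrane_ratio,membrane_width_um Optional membrane ring at the
#'   soma radius.
#' @param puncta_n,puncta_total_ratio,puncta_sigma_um Optional cytosolic
#'   puncta: count, summed intensity (x `peak_intensity`, split equally) and
#'   Gaussian radius.
#' @param render_radius_um Disc radius inside which the cell is rendered
#'   (default 20 um, the per-cell profiling radius).
#' @return A `staining_cell` list.
#' @export
staining_cell <- function(center, nucleus_radius_um = 3.5,
                          soma_radius_um = 10, nucleus_ratio = 0.05,
                          cytosol_ratio = 0.5, neuropil_ratio = 0.5,
                          membrane_ratio = 0, membrane_width_um = 0.5,
                          puncta_n = 0L, puncta_total_ratio = 0,
                          puncta_sigma_um = 0.4, render_radius_um = 20) {
  if (nucleus_radius_um >= soma_radius_um)
    stop("nucleus_radius_um must be smaller than soma_radius_um")
  if (soma_radius_um > render_radius_um)
    stop("soma_radius_um must not exceed render_radius_um")
  structure(list(center = as.numeric(center),
                 nucleus_radius_um = nucleus_radius_um,
                 soma_radius_um = soma_radius_um,
                 nucleus_ratio = nucleus_ratio, cytosol_ratio = cytosol_ratio,
                 neuropil_ratio = neuropil_ratio,
                 membrane_ratio = membrane_ratio,
                 membrane_width_um = membrane_width_um,
                 puncta_n = as.integer(puncta_n),
                 puncta_total_ratio = puncta_total_ratio,
                 puncta_sigma_um = puncta_sigma_um,
                 render_radius_um = render_radius_um),
            class = "staining_cell")
}

#' Generate a synthetic staining image
#'
#' @param spec A [staining_field_spec()].
#' @return Numeric matrix (rows x cols) of counts, with attributes
#'   `pixel_pitch` (um/px) and `injection_center` (um).
#' @export
generate_staining_field <- function(spec) {
  stopifnot(inherits(spec, "staining_field_spec"))
  fs <- spec$frame_size; pitch <- spec$pixel_pitch
  ru <- (0:(fs[1] - 1L)) * pitch            # pixel-centre positions, um
  cu <- (0:(fs[2] - 1L)) * pitch
  dr <- outer(ru - spec$injection_center[1], rep(1, fs[2]))
  dc <- outer(rep(1, fs[1]), cu - spec$injection_center[2])
  r <- sqrt(dr^2 + dc^2)
  sigma <- spec$half_max_radius_um / sqrt(2 * log(2))
  img <- spec$peak_intensity * exp(-r^2 / (2 * sigma^2))
  if (spec$profile_shape == "gaussian-with-tail")
    img <- img + spec$peak_intensity * spec$tail_fraction *
      exp(-r / spec$tail_scale_um)

  cell_jobs <- list()
  for (cl in spec$cells) {
    lim_r <- range(cl$center[1] + c(-1, 1) * cl$render_radius_um)
    lim_c <- range(cl$center[2] + c(-1, 1) * cl$render_radius_um)
    if (lim_r[1] < -pitch / 2 || lim_c[1] < -pitch / 2 ||
        lim_r[2] > (fs[1] - 0.5) * pitch || lim_c[2] > (fs[2] - 0.5) * pitch)
      stop("cell rendering disc overlaps the image border")
    cr <- sqrt((dr - (cl$center[1] - spec$injection_center[1]))^2 +
                 (dc - (cl$center[2] - spec$injection_center[2]))^2)
    add <- numeric(length(cr))
    add[cr < cl$nucleus_radius_um] <- cl$nucleus_ratio
    add[cr >= cl$nucleus_radius_um & cr < cl$soma_radius_um] <- cl$cytosol_ratio
    add[cr >= cl$soma_radius_um & cr < cl$render_radius_um] <- cl$neuropil_ratio
    add <- add * spec$peak_intensity
    if (cl$membrane_ratio > 0)
      add <- add + cl$membrane_ratio * spec$peak_intensity *
        exp(-(cr - cl$soma_radius_um)^2 / (2 * cl$membrane_width_um^2)) *
        (cr < cl$render_radius_um)
    cell_jobs[[length(cell_jobs) + 1L]] <- list(cl = cl, add = add, cr = cr)
    img <- img + matrix(add, fs[1], fs[2])
  }
  img <- with_seed(spec$seed, {
    # puncta placement and noise both consume the seeded stream
    for (job in cell_jobs) {
      cl <- job$cl
      if (cl$puncta_n > 0L && cl$puncta_total_ratio > 0) {
        per <- cl$puncta_total_ratio * spec$peak_intensity / cl$puncta_n
        ang <- stats::runif(cl$puncta_n, 0, 2 * pi)
        rad <- stats::runif(cl$puncta_n, cl$nucleus_radius_um, cl$soma_radius_um)
        for (k in seq_len(cl$puncta_n)) {
          pr <- cl$center[1] + rad[k] * cos(ang[k])
          pc <- cl$center[2] + rad[k] * sin(ang[k])
          d2 <- (dr - (pr - spec$injection_center[1]))^2 +
            (dc - (pc - spec$injection_center[2]))^2
          img <- img + per * exp(-d2 / (2 * cl$puncta_sigma_um^2))
        }
      }
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), sd = spec$noise_sd),
                          fs[1], fs[2])
    img
  })
  attr(img, "pixel_pitch") <- pitch
  attr(img, "injection_center") <- spec$injection_center
  img
}

#' Dye solution molarity from mass concentration
#'
#' `ug/ml` divided by molecular weight (`g/mol`) gives millimolar
#' concentration directly (ug/ml = mg/l; mM = (mg/l) / (g/mol)).
#'
#' @param mass_concentration_ug_ml Mass concentration in ug/ml.
#' @param molecular_weight Molecular weight in g/mol.
#' @return Molarity in mM.
#' @export
dye_solution_molarity <- function(mass_concentration_ug_ml, molecular_weight) {
  if (!is.numeric(mass_concentration_ug_ml) || mass_concentration_ug_ml <= 0)
    stop("mass_concentration_ug_ml must be positive")
  if (!is.numeric(molecular_weight) || molecular_weight <= 0)
    stop("molecular_weight must be positive")
  mass_concentration_ug_ml / molecular_weight
}
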