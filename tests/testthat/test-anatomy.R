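# Radial profiles, half-max radius, per-cell compartments, segment
# variability.

flat_image <- function(n = 64, value = 10, pitch = 1) {
  img <- matrix(value, n, n)
  attr(img, "pixel_pitch") <- pitch
  img
}

test_that("radial_profile: flat fields, point sources, annuli", {
  img <- flat_image()
  p <- radial_profile(img, c(31, 31), r_max_um = 25)
  expect_true(all(abs(p$intensity - 10) < 1e-12, na.rm = TRUE))

  pt <- flat_image(value = 0)
  pt[32, 32] <- 100
  pp <- radial_profile(pt, c(31, 31), r_max_um = 20)
  expect_equal(which.max(pp$intensity), 1L)

  # annulus of radius 15: profile peaks in the bin containing r = 15
  r <- sqrt((row(pt) - 32)^2 + (col(pt) - 32)^2)
  ann <- flat_image(value = 0)
  ann[r >= 14.5 & r < 15.5] <- 50
  pa <- radial_profile(ann, c(31, 31), r_max_um = 25)
  expect_close(pa$radii_um[which.max(pa$intensity)], 15, tol = 1)
  expect_error(radial_profile(img, c(-5, 0), 20), "outside")
})

test_that("radial_profile is rotation invariant on symmetric fields", {
  sp <- staining_field_spec(frame_size = c(81, 81), pixel_pitch = 1,
                            half_max_radius_um = 25)
  img <- generate_staining_field(sp)
  rot <- t(img)[, rev(seq_len(81))]         # 90-degree rotation
  attr(rot, "pixel_pitch") <- 1
  p1 <- radial_profile(img, c(40, 40), 35)
  p2 <- radial_profile(rot, c(40, 40), 35)
  expect_equal(p1$intensity, p2$intensity, tolerance = 1e-10)
})

test_that("half_max_radius: Gaussian closed form, top-hat, censoring", {
  # sigma = 100 um -> half max at sigma * sqrt(2 ln 2) = 117.7 um
  r <- seq(0.5, 400, by = 1)
  y <- exp(-r^2 / (2 * 100^2))
  prof <- structure(list(radii_um = r, intensity = y, center = c(0, 0),
                         bin_width_um = 1, normalization = "raw"),
                    class = "radial_profile")
  hm <- half_max_radius(prof)
  expect_close(as.numeric(hm), 100 * sqrt(2 * log(2)), tol = 1)
  expect_false(attr(hm, "censored"))

  th <- structure(list(radii_um = r, intensity = as.numeric(r <= 80),
                       center = c(0, 0), bin_width_um = 1,
                       normalization = "raw"), class = "radial_profile")
  expect_close(as.numeric(half_max_radius(th)), 80, tol = 1)

  inc <- structure(list(radii_um = r, intensity = r, center = c(0, 0),
                        bin_width_um = 1, normalization = "raw"),
                   class = "radial_profile")
  hmc <- half_max_radius(inc)
  expect_true(attr(hmc, "censored"))
})

test_that("configured half-max radii are recovered across seeds and noise", {
  for (seed in 1:10) {
    sp <- staining_field_spec(frame_size = c(161, 161), pixel_pitch = 2.8,
                              half_max_radius_um = 84, peak_intensity = 1000,
                              noise_sd = 20, seed = seed)
    img <- generate_staining_field(sp)
    prof <- radial_profile(img, attr(img, "injection_center"), r_max_um = 220)
    expect_close(as.numeric(half_max_radius(prof)), 84, tol = 2.8) # one bin
  }
})

test_that("cell profiles: symmetry, normalization, membrane ring peak", {
  # high-magnification confocal geometry: 0.5 um pixels, 50 um frame
  cell <- staining_cell(c(25, 25), cytosol_ratio = 1, neuropil_ratio = 0.4,
                        membrane_ratio = 2, membrane_width_um = 1)
  sp <- staining_field_spec(frame_size = c(101, 101), pixel_pitch = 0.5,
                            half_max_radius_um = 1e6, peak_intensity = 100,
                            cells = list(cell))
  img <- generate_staining_field(sp)
  cp <- cell_radial_profile(img, c(25, 25))
  expect_equal(max(cp$average$intensity, na.rm = TRUE), 1)
  # rotational symmetry: every segment matches the average away from the
  # centre (innermost bins hold a handful of pixels per segment)
  outer_bins <- 5:nrow(cp$segments)
  for (j in seq_len(ncol(cp$segments)))
    expect_lt(max(abs(cp$segments[outer_bins, j] -
                        cp$average$intensity[outer_bins]), na.rm = TRUE), 0.1)
  # membrane ring at the soma radius (10 um) dominates the profile
  pk <- cp$radii_um[which.max(cp$average$intensity)]
  expect_close(pk, 10, tol = 1)
  expect_error(cell_radial_profile(img, c(5, 25)), "clipped")
})

# a cell rendered far from a tightly confined injection field, so the
# compartment intensities are the rendered ratios alone
isolated_cell_image <- function(cell, noise_sd = 0, seed = 1) {
  sp <- staining_field_spec(frame_size = c(101, 101), pixel_pitch = 0.5,
                            injection_center = c(2, 2),
                            half_max_radius_um = 1, peak_intensity = 100,
                            cells = list(cell), noise_sd = noise_sd,
                            seed = seed)
  generate_staining_field(sp)
}

test_that("compartment statistics recover rendered contrast ratios", {
  # uniform image: ratio 1
  cpu <- cell_radial_profile(flat_image(101, pitch = 0.5), c(25, 25),
                             normalize = FALSE)
  stu <- compartment_stats(cpu)
  expect_equal(stu$per_cell$cytosol_neuropil_ratio, 1, tolerance = 1e-10)

  # strongly internalized cell: cytosol twice the neuropil
  cell <- staining_cell(c(25, 25), cytosol_ratio = 0.8, neuropil_ratio = 0.4)
  cp <- cell_radial_profile(isolated_cell_image(cell), c(25, 25),
                            normalize = FALSE)
  st <- compartment_stats(cp)
  expect_close(st$per_cell$cytosol_neuropil_ratio, 2, tol = 0.15)
  expect_true(st$per_cell$cytosol_dominant)
  expect_equal(st$fraction_cytosol_dominant, 1)

  # nucleus-confined signal: cytosol and neuropil sit at background (~0)
  nuc <- staining_cell(c(25, 25), nucleus_ratio = 1, cytosol_ratio = 0,
                       neuropil_ratio = 0)
  cpn <- cell_radial_profile(isolated_cell_image(nuc), c(25, 25),
                             normalize = FALSE)
  stn <- compartment_stats(cpn)
  expect_gt(stn$per_cell$nucleus, 50)
  expect_lt(stn$per_cell$cytosol, 2)
  expect_lt(stn$per_cell$neuropil, 2)
})

test_that("compartment stats invariant to constant background after min-max", {
  cell <- staining_cell(c(25, 25), cytosol_ratio = 0.8, neuropil_ratio = 0.4)
  img <- isolated_cell_image(cell)
  shifted <- img + 55
  attr(shifted, "pixel_pitch") <- 0.5
  s1 <- compartment_stats(cell_radial_profile(img, c(25, 25)))
  s2 <- compartment_stats(cell_radial_profile(shifted, c(25, 25)))
  expect_equal(s1$per_cell$cytosol, s2$per_cell$cytosol, tolerance = 1e-10)
  expect_equal(s1$per_cell$neuropil, s2$per_cell$neuropil, tolerance = 1e-10)
})

test_that("segment variability tracks labeling homogeneity", {
  sym <- staining_cell(c(40, 40), cytosol_ratio = 1, neuropil_ratio = 0.5)
  sp0 <- staining_field_spec(frame_size = c(81, 81), pixel_pitch = 1,
                             half_max_radius_um = 1e6, peak_intensity = 100,
                             cells = list(sym))
  v_sym <- segment_variability(
    cell_radial_profile(generate_staining_field(sp0), c(40, 40)))
  expect_lt(v_sym, 0.05)

  # dispersion falls as fixed total intensity spreads over more puncta
  v_of <- function(n_puncta, seed) {
    cl <- staining_cell(c(40, 40), cytosol_ratio = 0.3, neuropil_ratio = 0.3,
                        puncta_n = n_puncta, puncta_total_ratio = 3)
    sp <- staining_field_spec(frame_size = c(81, 81), pixel_pitch = 1,
                              half_max_radius_um = 1e6, peak_intensity = 100,
                              cells = list(cl), seed = seed)
    segment_variability(
      cell_radial_profile(generate_staining_field(sp), c(40, 40)))
  }
  v1 <- mean(vapply(1:5, function(s) v_of(1L, s), numeric(1)))
  v6 <- mean(vapply(1:5, function(s) v_of(6L, s), numeric(1)))
  v30 <- mean(vapply(1:5, function(s) v_of(30L, s), numeric(1)))
  expect_gt(v1, v_sym)
  expect_true(v1 > v6 && v6 > v30)
})
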