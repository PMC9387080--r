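# Shared fixtures, built in code. Heavy noise-free volumes are memoized per
# test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small cylindrical phantom with one sphere, zero background
one_sphere_spec <- function(diameter_mm = 20, conc = 10, background = 0) {
  phantom_spec("one_sphere",
               list(semi_axes = c(60, 60), length = 100), background,
               inserts = list(sphere_insert(c(0, 0, 0), diameter_mm, conc,
                                            "s1")))
}

small_grid <- function(voxel = c(2, 2, 2), dims = c(40, 40, 40)) {
  grid_spec(voxel, dims)
}

# uniform warm phantom on a coarse grid (for noise statistics; interior
# holds > 1e4 fully-filled voxels)
uniform_spec <- function(conc = 3) {
  phantom_spec("uniform", list(semi_axes = c(40, 40), length = 80), conc)
}

uniform_grid <- function() grid_spec(c(3, 3, 3), c(30, 30, 30))

# a uniform activity_volume without any phantom geometry
flat_volume <- function(value, voxel = c(2, 2, 2), dims = c(16, 16, 16)) {
  g <- grid_spec(voxel, dims)
  activity_volume(array(value, dims), g)
}

# default study conditions, memoized: noise-free soft-tissue volume after
# the TOF system PSF, plus the background layout
soft_tissue_conditions <- function() {
  memo("soft_tissue_conditions", {
    spec <- phantom_preset("soft_tissue")
    grid <- grid_preset("3.30")
    acq <- acquisition_preset("tof")
    nf <- apply_psf(voxelize_phantom(spec, grid, 4), acq$psf_fwhm_mm)
    layout <- nema_background_layout(spec$body, spec$inserts, grid)
    list(spec = spec, grid = grid, acq = acq, noise_free = nf,
         layout = layout)
  })
}

# small two-line resolution fixture (cheap stand-in for the full 0.83 grid)
mini_resolution <- function(psf_fwhm = 3.6) {
  memo(paste0("mini_resolution_", psf_fwhm), {
    spec <- phantom_spec("mini_res",
                         list(semi_axes = c(150, 100), length = 60), 0,
                         lines = list(line_source(10, 0.5, 7100, 40),
                                      line_source(100, 0.5, 7100, 40)))
    g <- grid_spec(c(0.83, 0.83, 2), c(170, 40, 24),
                   origin_mm = c(55 - 0.83 * 169 / 2, -0.83 * 39 / 2,
                                 -23))
    list(spec = spec, grid = g,
         vol = apply_psf(voxelize_phantom(spec, g, 8), psf_fwhm))
  })
}

# hand cohort used for oracle comparisons (n = 6)
hand_pairs <- function() {
  paired_measurements(data.frame(
    lesion_id = paste0("L", 1:6),
    value_full = c(3.2, 5.8, 9.1, 14.5, 21.0, 33.7),
    value_reduced = c(3.0, 5.9, 8.6, 14.1, 20.1, 32.4)))
}
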