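test_that("spherical VOI mean and max behave on uniform and spiked fields", {
  vol <- flat_volume(7)
  voi <- spherical_voi(c(0, 0, 0), 10)
  expect_equal(voi_mean(vol, voi), 7)
  expect_equal(voi_max(vol, voi), 7)
  spiked <- vol
  spiked$values[8, 8, 8] <- 42
  expect_equal(voi_max(spiked, voi), 42)
  expect_gt(voi_max(spiked, voi), voi_mean(spiked, voi))
  # VOI smaller than a voxel, centered between voxel centers
  expect_error(voi_mean(vol, spherical_voi(c(0, 0, 0), 0.5)), "empty")
})

test_that("a VOI fully outside the body of a cold phantom reads zero", {
  spec <- phantom_spec("short", list(semi_axes = c(60, 60), length = 60), 0,
                       inserts = list(sphere_insert(c(0, 0, 0), 20, 10, "s")))
  vol <- voxelize_phantom(spec, small_grid(), 4)
  expect_equal(voi_mean(vol, spherical_voi(c(0, 0, -36), 6)), 0)
})

test_that("voi_max never falls below voi_mean for the preset spheres", {
  cond <- soft_tissue_conditions()
  sim <- simulate_time_series(cond$spec, cond$grid, cond$acq, seed = 21,
                              noise_free = cond$noise_free)
  vol <- sim$volumes[[1]]
  for (s in cond$spec$inserts) {
    voi <- spherical_voi(s$center, s$diameter)
    expect_gte(voi_max(vol, voi), voi_mean(vol, voi))
  }
})

test_that("the 1-mL peak VOI has the closed-form diameter and spills out of small spheres", {
  expect_equal(PEAK_VOI_DIAMETER_MM, 12.407, tolerance = 1e-4)
  expect_equal(sphere_diameter_from_volume(1), PEAK_VOI_DIAMETER_MM)
  vol <- flat_volume(5)
  expect_equal(peak_voi_value(vol, c(0, 0, 0)), 5)
  # 8.5-mm sphere blurred: the 1-mL VOI includes background, so peak < max
  spec <- phantom_spec("s85", list(semi_axes = c(60, 60), length = 100), 0,
                       inserts = list(sphere_insert(c(0, 0, 0), 8.5, 15, "s")))
  g <- grid_spec(c(1.65, 1.65, 2), c(48, 48, 40))
  blurred <- apply_psf(voxelize_phantom(spec, g, 4), 3.6)
  voi <- spherical_voi(c(0, 0, 0), 8.5)
  expect_lt(peak_voi_value(blurred, c(0, 0, 0)), voi_max(blurred, voi))
})

test_that("the default background layout has 60 clear ROIs on 5 planes", {
  cond <- soft_tissue_conditions()
  layout <- nema_background_layout(cond$spec$body, cond$spec$inserts,
                                   cond$grid)
  expect_equal(nrow(layout), 60)
  expect_length(attr(layout, "plane_indices"), 5)
  expect_true(all(layout$diameter_mm == 37))
  # constructive invariant: every ROI clear of every (dilated) insert
  for (n in seq_len(nrow(layout))) {
    for (s in cond$spec$inserts) {
      d <- sqrt(sum((c(layout$center_x[n], layout$center_y[n]) -
                       s$center[1:2])^2))
      expect_gte(d, 37 / 2 + s$diameter / 2)
    }
  }
  single <- nema_background_layout(cond$spec$body, cond$spec$inserts,
                                   cond$grid, planes_each_side = 0)
  expect_equal(nrow(single), 12)
})

test_that("infeasible ROI placement fails with the violated constraints", {
  cond <- soft_tissue_conditions()
  blocking <- list(sphere_insert(c(105, 0, 0), 28, 15, "blocker"))
  expect_error(
    nema_background_layout(cond$spec$body, blocking, cond$grid),
    "blocker")
  tiny_body <- list(semi_axes = c(30, 30), length = 100, center = c(0, 0, 0))
  expect_error(nema_background_layout(tiny_body, list(), cond$grid),
               "too small")
})

test_that("background statistics match closed forms", {
  cond <- soft_tissue_conditions()
  g <- cond$grid
  layout <- nema_background_layout(cond$spec$body, cond$spec$inserts, g)
  vol <- flat_volume(4.5, voxel = g$voxel_size_mm, dims = g$dims)
  st <- background_stats(vol, layout)
  expect_equal(st$c_bgr, 4.5)
  expect_equal(st$sd_bgr, 0)
  expect_gt(st$n_voxels, 1000)
  # two symmetric ROIs over a half-and-half field: mean (a+b)/2, SD |a-b|/2
  tmpl <- matrix(c(60, 0, -60, 0), ncol = 2, byrow = TRUE)
  lay2 <- nema_background_layout(cond$spec$body, list(), g, per_plane = 2,
                                 planes_each_side = 0, template = tmpl)
  vol2 <- vol
  xs <- grid_axis(g, 1)
  vol2$values[xs > 0, , ] <- 10
  vol2$values[xs < 0, , ] <- 2
  st2 <- background_stats(vol2, lay2)
  expect_equal(st2$c_bgr, 6)
  expect_equal(st2$sd_bgr, 4)
})

test_that("background SD on a simulated frame matches the Poisson model", {
  cond <- soft_tissue_conditions()
  sim <- simulate_time_series(cond$spec, cond$grid, cond$acq, seed = 17,
                              noise_free = cond$noise_free)
  ref_raw <- sim$reference   # unfiltered reference frame
  st <- background_stats(ref_raw, cond$layout)
  kappa <- cond$acq$sensitivity_kappa
  pred_sd <- sqrt(3 / (voxel_volume_mL(cond$grid) * kappa * 600))
  # voxelwise SD of independent Poisson concentrations; SE of SD ~ sd/sqrt(2n)
  se <- pred_sd / sqrt(2 * st$n_voxels)
  expect_lt(abs(st$sd_bgr - pred_sd), 4 * se + 0.02 * pred_sd)
})

test_that("50%-isocontour recovers sphere volumes and respects connectivity", {
  sp <- one_sphere_spec(20, 10)
  g <- grid_spec(c(1.65, 1.65, 2), c(64, 64, 48))
  vol <- voxelize_phantom(sp, g, 4)
  iso <- isocontour_50(vol, c(0, 0, 0))
  expect_equal(iso$volume_mL, 4.19, tolerance = 0.10)
  # two disjoint hot spheres: only the seeded one is segmented
  sp2 <- phantom_spec("two", list(semi_axes = c(60, 60), length = 100), 0,
                      inserts = list(sphere_insert(c(-25, 0, 0), 16, 10, "a"),
                                     sphere_insert(c(25, 0, 0), 16, 10, "b")))
  vol2 <- voxelize_phantom(sp2, g, 4)
  iso2 <- isocontour_50(vol2, c(-25, 0, 0))
  idx_b <- which(iso2$mask, arr.ind = TRUE)
  xs <- grid_axis(g, 1)[idx_b[, 1]]
  expect_true(all(xs < 0))
  # uniform field: threshold is below the field value, whole body segmented
  spu <- uniform_spec(3)
  volu <- voxelize_phantom(spu, uniform_grid(), 2)
  isou <- isocontour_50(volu, c(0, 0, 0))
  expect_equal(sum(isou$mask), sum(volu$values >= 0.5 * max(volu$values)))
  # seed in a cold region fails
  expect_error(isocontour_50(vol, c(0, 0, -40)), "empty segmentation")
})

test_that("isocontour volume is monotone non-increasing in the threshold", {
  vol <- apply_psf(voxelize_phantom(one_sphere_spec(20, 10),
                                    small_grid(), 4), 3)
  fr <- c(0.3, 0.5, 0.7)
  vols <- vapply(fr, function(f)
    isocontour_50(vol, c(0, 0, 0), threshold_fraction = f)$volume_mL, 0)
  expect_true(all(diff(vols) <= 0))
})

test_that("horseshoe background reads the surrounding activity", {
  spec <- phantom_spec("hs", list(semi_axes = c(60, 60), length = 100), 3,
                       inserts = list(sphere_insert(c(0, 0, 0), 15, 15, "s")))
  g <- grid_spec(c(1.65, 1.65, 2), c(64, 64, 48))
  vol <- apply_psf(voxelize_phantom(spec, g, 4), 4)
  lesion <- isocontour_50(vol, c(0, 0, 0))$mask
  hs <- horseshoe_background(vol, lesion, gap_mm = 3)
  expect_equal(hs, 3, tolerance = 0.05)
  # on a uniform field any shell reads the field value, with or without wedge
  volu <- flat_volume(2.5, voxel = c(2, 2, 2), dims = c(32, 32, 32))
  mask <- array(FALSE, dim(volu$values)); mask[16:17, 16:17, 16:17] <- TRUE
  expect_equal(horseshoe_background(volu, mask), 2.5)
  expect_equal(horseshoe_background(volu, mask, opening_fraction = 0), 2.5)
})

test_that("sphere volume and diameter conversions are exact inverses", {
  expect_equal(round(sphere_diameter_from_volume(0.7)), 11)
  expect_equal(sphere_diameter_from_volume(1.0), 12.407, tolerance = 1e-4)
  d <- c(6.5, 9.7, 12.6, 15.1, 22.2, 28.0)
  expect_equal(sphere_diameter_from_volume(sphere_volume_from_diameter(d)), d,
               tolerance = 1e-12)
  expect_error(sphere_diameter_from_volume(0), "> 0")
  expect_error(sphere_volume_from_diameter(-1), "> 0")
})
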