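#' Spherical volume of interest
#'
#' @param center_mm World center (mm).
#' @param diameter_mm Diameter (mm), > 0.
#' @return Object of class `spherical_voi`.
#' @export
spherical_voi <- function(center_mm, diameter_mm) {
  if (diameter_mm <= 0) stop("VOI diameter must be > 0")
  structure(list(center = as.numeric(center_mm), diameter = diameter_mm),
            class = "spherical_voi")
}

# linear indices of voxels whose centers lie inside a sphere
sphere_voxel_indices <- function(grid, center, diameter) {
  r <- diameter / 2
  rng <- bbox_index_range(grid, center - r, center + r)
  if (is.null(rng)) return(integer(0))
  xs <- grid_axis(grid, 1)[rng$i] - center[1]
  ys <- grid_axis(grid, 2)[rng$j] - center[2]
  zs <- grid_axis(grid, 3)[rng$k] - center[3]
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  sel <- which(d2 <= r^2, arr.ind = TRUE)
  if (nrow(sel) == 0) return(integer(0))
  i <- rng$i[sel[, 1]]; j <- rng$j[sel[, 2]]; k <- rng$k[sel[, 3]]
  (k - 1L) * grid$dims[1] * grid$dims[2] + (j - 1L) * grid$dims[1] + i
}

#' Mean activity concentration inside a spherical VOI
#'
#' Membership rule: a voxel belongs to the VOI iff its center lies inside
#' the analytic sphere (mirrors clinical analysis tools; no partial-volume
#' weighting).
#'
#' @param vol An [activity_volume()].
#' @param voi A [spherical_voi()].
#' @return Mean concentration (kBq/mL).
#' @export
voi_mean <- function(vol, voi) {
  idx <- sphere_voxel_indices(vol$grid, voi$center, voi$diameter)
  if (length(idx) == 0)
    stop("VOI contains no voxel centers (empty VOI)")
  mean(vol$values[idx])
}

#' Maximum activity concentration inside a spherical VOI
#'
#' @inheritParams voi_mean
#' @return Maximum concentration (kBq/mL) over voxel centers in the sphere.
#' @export
voi_max <- function(vol, voi) {
  idx <- sphere_voxel_indices(vol$grid, voi$center, voi$diameter)
  if (length(idx) == 0)
    stop("VOI contains no voxel centers (empty VOI)")
  max(vol$values[idx])
}

#' Diameter of the 1-mL peak VOI (mm)
#'
#' The peak VOI is a sphere of exactly 1 mL volume; its diameter is
#' `(6 * 1000 / pi)^(1/3)` = 12.407 mm.
#' @export
PEAK_VOI_DIAMETER_MM <- (6 * 1000 / pi)^(1 / 3)

#' Peak activity concentration
#'
#' Mean concentration in a 1-mL sphere centered exactly at the insert center
#' (not at the hottest voxel; `center_on_max = TRUE` switches to the
#' max-centered convention used for patient-style data).
#'
#' @param vol An [activity_volume()].
#' @param insert_center_mm World center (mm) of the phantom insert.
#' @param center_on_max If TRUE, re-center the peak sphere on the hottest
#'   voxel within the 1-mL sphere around `insert_center_mm`. Default FALSE.
#' @return Peak concentration (kBq/mL).
#' @export
peak_voi_value <- function(vol, insert_center_mm, center_on_max = FALSE) {
  d <- PEAK_VOI_DIAMETER_MM
  center <- as.numeric(insert_center_mm)
  if (center_on_max) {
    idx <- sphere_voxel_indices(vol$grid, center, d)
    if (length(idx) == 0) stop("peak VOI contains no voxel centers")
    hot <- idx[which.max(vol$values[idx])]
    k <- (hot - 1L) %/% (vol$grid$dims[1] * vol$grid$dims[2])
    rem <- (hot - 1L) %% (vol$grid$dims[1] * vol$grid$dims[2])
    j <- rem %/% vol$grid$dims[1]; i <- rem %% vol$grid$dims[1]
    center <- vol$grid$origin_mm + c(i, j, k) * vol$grid$voxel_size_mm
  }
  voi_mean(vol, spherical_voi(center, d))
}

#' Sphere volume/diameter conversions
#'
#' `sphere_volume_from_diameter()` returns the volume in mL of a sphere of
#' diameter `d_mm`; `sphere_diameter_from_volume()` is its exact inverse,
#' `d = 10 * (6 V / pi)^(1/3)` with V in mL.
#'
#' @param d_mm Sphere diameter in mm (> 0).
#' @return Volume in mL.
#' @export
sphere_volume_from_diameter <- function(d_mm) {
  if (any(d_mm <= 0)) stop("diameter must be > 0")
  pi / 6 * (d_mm / 10)^3
}

#' @rdname sphere_volume_from_diameter
#' @param volume_mL Sphere volume in mL (> 0).
#' @return Diameter in mm.
#' @export
sphere_diameter_from_volume <- function(volume_mL) {
  if (any(volume_mL <= 0)) stop("volume must be > 0")
  10 * (6 * volume_mL / pi)^(1 / 3)
}
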