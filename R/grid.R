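#' Image grid specification
#'
#' Defines a regular 3-D sampling grid in scanner (world) coordinates. World
#' coordinates are in mm, voxel indices are 1-based in R, and the `origin` is
#' the world coordinate of the *center* of the first voxel.
#'
#' @param voxel_size_mm Numeric length-3 vector of voxel edge lengths (mm).
#' @param dims Integer length-3 vector of grid dimensions.
#' @param origin_mm World coordinate (mm) of the center of voxel (1,1,1).
#'   Defaults to centering the grid on the world origin.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(voxel_size_mm, dims, origin_mm = NULL) {
  voxel_size_mm <- as.numeric(voxel_size_mm)
  dims <- as.integer(dims)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive numbers (mm)")
  if (length(dims) != 3L || any(is.na(dims)) || any(dims <= 0L))
    stop("dims must be 3 positive integers")
  if (is.null(origin_mm)) origin_mm <- -voxel_size_mm * (dims - 1) / 2
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L) stop("origin_mm must be a 3-vector")
  structure(list(voxel_size_mm = voxel_size_mm, dims = dims,
                 origin_mm = origin_mm),
            class = "grid_spec")
}

#' Named reconstruction grid presets
#'
#' Three voxel-size presets used throughout: `"3.30"` (3.30 x 3.30 x 3.00 mm,
#' the standard clinical matrix), `"1.65"` (1.65 x 1.65 x 2.00 mm, the fine
#' clinical matrix) and `"0.83"` (0.83 x 0.83 x 2.00 mm, used for spatial
#' resolution only). All grids are centered on the world origin and enclose
#' the default torso body with at least a few voxels of padding.
#'
#' @param name One of `"3.30"`, `"1.65"`, `"0.83"`.
#' @return A [grid_spec()].
#' @export
grid_preset <- function(name = c("3.30", "1.65", "0.83")) {
  name <- match.arg(name)
  switch(name,
    "3.30" = grid_spec(c(3.30, 3.30, 3.00), c(96L, 64L, 64L)),
    "1.65" = grid_spec(c(1.65, 1.65, 2.00), c(192L, 128L, 96L)),
    "0.83" = grid_spec(c(0.83, 0.83, 2.00), c(380L, 250L, 96L)))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels of %.2f x %.2f x %.2f mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

# voxel-center coordinates along one axis (mm)
grid_axis <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$dims[axis]) - 1) * grid$voxel_size_mm[axis]
}

#' Voxel volume of a grid in mL
#' @param grid A [grid_spec()].
#' @return Voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_mL <- function(grid) prod(grid$voxel_size_mm) / 1000

# world-space bounding box [lo, hi] of the grid, including voxel half-widths
grid_bbox <- function(grid) {
  lo <- grid$origin_mm - grid$voxel_size_mm / 2
  hi <- grid$origin_mm + (grid$dims - 1 + 0.5) * grid$voxel_size_mm
  rbind(lo = lo, hi = hi)
}

# nearest voxel index (1-based) for world coordinates; no clamping
world_to_index <- function(grid, p) {
  round((p - grid$origin_mm) / grid$voxel_size_mm) + 1
}

#' Activity volume container
#'
#' A 3-D grid of activity concentration values in kBq/mL together with its
#' [grid_spec()] and free-form provenance metadata (phantom id, acquisition
#' time, reconstruction preset, seed).
#'
#' @param values 3-D numeric array (kBq/mL), non-negative.
#' @param grid A [grid_spec()] whose `dims` match `dim(values)`.
#' @param meta Named list of provenance fields.
#' @param counts Optional raw count array (same shape) kept for thinning.
#' @return An object of class `activity_volume`.
#' @export
activity_volume <- function(values, grid, meta = list(), counts = NULL) {
  if (!identical(dim(values), as.integer(grid$dims)))
    stop("values shape does not match grid dims")
  if (any(values < 0)) stop("activity concentrations must be >= 0")
  structure(list(values = values, grid = grid, meta = meta, counts = counts),
            class = "activity_volume")
}

#' @export
print.activity_volume <- function(x, ...) {
  cat(sprintf("<activity_volume> %d x %d x %d, range [%.3g, %.3g] kBq/mL\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values)))
  if (length(x$meta)) {
    keys <- names(x$meta)
    cat("  meta:", paste(sprintf("%s=%s", keys, vapply(x$meta, function(v)
      paste(format(v), collapse = ","), "")), collapse = " "), "\n")
  }
  invisible(x)
}

# trilinear interpolation of an activity_volume at world points (n x 3 matrix)
interp3 <- function(vol, pts) {
  pts <- matrix(pts, ncol = 3)
  g <- vol$grid
  u <- sweep(sweep(pts, 2, g$origin_mm), 2, g$voxel_size_mm, "/")  # 0-based
  if (any(u < 0) || any(sweep(u, 2, g$dims - 1) > 1e-9))
    stop("interpolation point outside grid")
  i0 <- pmin(floor(u), matrix(rep(g$dims - 2, each = nrow(u)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- u - i0
  v <- vol$values
  idx <- function(dx, dy, dz) {
    v[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
  }
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    out <- out + w * idx(dx, dy, dz)
  }
  out
}
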