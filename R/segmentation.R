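# dilate a logical 3-D mask by the 26-neighborhood
dilate26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    tx <- sx - dx; ty <- sy - dy; tz <- sz - dz
    out[sx, sy, sz] <- out[sx, sy, sz] | mask[tx, ty, tz]
  }
  out
}

# 26-connected component of `mask` containing the voxel at index `start`
connected_component <- function(mask, start) {
  comp <- array(FALSE, dim(mask))
  comp[start[1], start[2], start[3]] <- TRUE
  repeat {
    grown <- dilate26(comp) & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

#' 50%-of-maximum 3-D isocontour segmentation
#'
#' Segments the lesion around a seed point with a relative threshold: the
#' threshold is `threshold_fraction` times the local maximum, where the local
#' maximum is taken within the 26-connected super-threshold region grown from
#' the seed (threshold and region are iterated to a fixed point). Returns the
#' component mask and its volume.
#'
#' @param vol An [activity_volume()].
#' @param seed_point_mm World coordinates (mm) of a point inside the lesion.
#' @param threshold_fraction Fraction of the local maximum (default 0.5).
#' @return List with `mask` (logical array), `volume_mL`, `threshold`
#'   (kBq/mL) and `local_max` (kBq/mL).
#' @export
isocontour_50 <- function(vol, seed_point_mm, threshold_fraction = 0.5) {
  g <- vol$grid
  start <- world_to_index(g, as.numeric(seed_point_mm))
  if (any(start < 1) || any(start > g$dims))
    stop("seed point outside grid")
  m0 <- vol$values[start[1], start[2], start[3]]
  local_max <- m0
  repeat {
    thr <- threshold_fraction * local_max
    if (m0 < thr)
      stop("seed voxel below the threshold of its region (empty segmentation)")
    comp <- connected_component(vol$values >= thr, start)
    new_max <- max(vol$values[comp])
    if (new_max <= local_max) break
    local_max <- new_max
  }
  list(mask = comp, volume_mL = sum(comp) * voxel_volume_mL(g),
       threshold = threshold_fraction * local_max, local_max = local_max)
}

#' Horseshoe-shaped background value around a lesion
#'
#' Emulates the horseshoe background VOIs drawn around clinical lesions: a
#' spherical shell starting `gap_mm` beyond the lesion surface with the given
#' radial `thickness_mm`, with a solid-angle wedge of `opening_fraction`
#' removed around `opening_axis` (the open side of the horseshoe). The exact
#' shape parameters are package conventions, all configurable.
#'
#' @param vol An [activity_volume()].
#' @param lesion_mask Logical array (same shape) marking the lesion.
#' @param gap_mm Gap between lesion surface and shell (mm), default 3.
#' @param thickness_mm Radial shell thickness (mm), default 10.
#' @param opening_fraction Fraction (0-1) of the solid angle removed,
#'   default 0.25.
#' @param opening_axis Direction (3-vector) of the removed wedge, default +x.
#' @return Mean concentration (kBq/mL) over the shell.
#' @export
horseshoe_background <- function(vol, lesion_mask, gap_mm = 3,
                                 thickness_mm = 10, opening_fraction = 0.25,
                                 opening_axis = c(1, 0, 0)) {
  if (opening_fraction < 0 || opening_fraction >= 1)
    stop("opening_fraction must be in [0, 1)")
  g <- vol$grid
  les <- which(lesion_mask, arr.ind = TRUE)
  if (nrow(les) == 0) stop("empty lesion mask")
  les_mm <- sweep(sweep(les - 1, 2, g$voxel_size_mm, "*"), 2, g$origin_mm, "+")
  centroid <- colMeans(les_mm)
  # candidate voxels: lesion bbox expanded by gap + thickness
  pad <- gap_mm + thickness_mm
  rng <- bbox_index_range(g, apply(les_mm, 2, min), apply(les_mm, 2, max),
                          margin = pad)
  centers <- as.matrix(expand.grid(grid_axis(g, 1)[rng$i],
                                   grid_axis(g, 2)[rng$j],
                                   grid_axis(g, 3)[rng$k]))
  # distance from each candidate to the lesion surface (nearest lesion voxel)
  dmin <- rep(Inf, nrow(centers))
  block <- 512L
  for (b in seq(1, nrow(les_mm), by = block)) {
    sub <- les_mm[b:min(b + block - 1L, nrow(les_mm)), , drop = FALSE]
    d2 <- outer(rowSums(centers^2), rep(1, nrow(sub))) -
      2 * centers %*% t(sub) + outer(rep(1, nrow(centers)), rowSums(sub^2))
    dmin <- pmin(dmin, sqrt(pmax(apply(d2, 1, min), 0)))
  }
  in_shell <- dmin > gap_mm & dmin <= gap_mm + thickness_mm
  if (opening_fraction > 0) {
    ax <- opening_axis / sqrt(sum(opening_axis^2))
    v <- sweep(centers, 2, centroid)
    cosang <- (v %*% ax) / pmax(sqrt(rowSums(v^2)), 1e-12)
    # wedge: cap of solid angle opening_fraction * 4pi around the axis
    cos_cut <- 1 - 2 * opening_fraction
    in_shell <- in_shell & as.numeric(cosang) < cos_cut
  }
  if (!any(in_shell)) stop("horseshoe shell is empty")
  vals <- vol$values[rng$i, rng$j, rng$k]
  mean(vals[in_shell])
}
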