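# Default in-plane template for the 12 background ROI centers (mm, relative
# to the body center). The exact in-plane positions are a documented fixture:
# they satisfy the stated constraints (>= 15 mm clearance from the body edge
# in addition to the ROI radius, and >= ROI radius + largest sphere radius
# from every insert center) for the default torso and sphere ring, in the
# spirit of the NEMA NU 2-2012 background ROI scheme.
NEMA_ROI_TEMPLATE_MM <- matrix(c(
   105,   0,
  -105,   0,
    85,  42,
    85, -42,
   -85,  42,
   -85, -42,
    40,  62,
    40, -62,
   -40,  62,
   -40, -62,
     0,  24,
     0, -24), ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("x", "y")))

#' NEMA-style background ROI layout
#'
#' Places circular background ROIs (default 37-mm diameter, 12 per plane) in
#' the axial plane through the sphere centers and `planes_each_side` adjacent
#' slices in each direction (5 planes and 60 ROIs by default). Placement uses
#' a fixed in-plane template and is validated against the body margin and
#' insert-clearance constraints.
#'
#' @param body Body geometry list (as in [phantom_spec()]).
#' @param inserts List of [sphere_insert()] to keep clear of.
#' @param grid A [grid_spec()].
#' @param roi_diameter_mm ROI diameter (mm), default 37.
#' @param per_plane ROIs per plane, default 12 (at most the template size).
#' @param planes_each_side Adjacent slices on each side of the central
#'   plane, default 2.
#' @param template In-plane ROI centers (n x 2 matrix, mm); default the
#'   shipped template.
#' @param edge_margin_mm Required clearance between ROI edge and body edge
#'   (default 15).
#' @return Object of class `roi_layout`: a data frame of ROI centers with
#'   plane indices, plus attributes `roi_diameter_mm` and `plane_indices`.
#' @export
nema_background_layout <- function(body, inserts, grid,
                                   roi_diameter_mm = 37, per_plane = 12L,
                                   planes_each_side = 2L,
                                   template = NEMA_ROI_TEMPLATE_MM,
                                   edge_margin_mm = 15) {
  r_roi <- roi_diameter_mm / 2
  if (per_plane > nrow(template))
    stop("per_plane exceeds the number of template positions")
  tpl <- template[seq_len(per_plane), , drop = FALSE]
  # constraint checks
  viol <- character(0)
  shrink_a <- body$semi_axes[1] - r_roi - edge_margin_mm
  shrink_b <- body$semi_axes[2] - r_roi - edge_margin_mm
  if (shrink_a <= 0 || shrink_b <= 0)
    stop("body too small to host background ROIs with the required margin")
  max_sphere_r <- if (length(inserts)) max(vapply(inserts, function(s)
    s$diameter, 0)) / 2 else 0
  for (n in seq_len(nrow(tpl))) {
    p <- tpl[n, ]
    if ((p[1] / shrink_a)^2 + (p[2] / shrink_b)^2 > 1)
      viol <- c(viol, sprintf("ROI %d too close to the body edge", n))
    for (s in inserts) {
      d <- sqrt(sum((p - s$center[1:2])^2))
      if (d < r_roi + max_sphere_r)
        viol <- c(viol, sprintf("ROI %d within clearance of insert '%s'",
                                n, s$label))
    }
  }
  if (length(viol))
    stop("infeasible background ROI placement:\n  ",
         paste(unique(viol), collapse = "\n  "))
  # plane selection: slice through the mean insert z, +/- adjacent slices
  z_ins <- if (length(inserts))
    mean(vapply(inserts, function(s) s$center[3], 0)) else 0
  zc <- which.min(abs(grid_axis(grid, 3) - z_ins))
  planes <- (zc - planes_each_side):(zc + planes_each_side)
  if (any(planes < 1L) || any(planes > grid$dims[3]))
    stop("background planes fall outside the grid")
  rois <- expand.grid(n = seq_len(per_plane), plane_index = planes)
  out <- data.frame(center_x = tpl[rois$n, 1] + body$center[1],
                    center_y = tpl[rois$n, 2] + body$center[2],
                    plane_index = rois$plane_index,
                    z_mm = grid_axis(grid, 3)[rois$plane_index],
                    diameter_mm = roi_diameter_mm)
  structure(out, class = c("roi_layout", "data.frame"),
            roi_diameter_mm = roi_diameter_mm, plane_indices = planes)
}

# linear voxel indices of the union of all ROI discs in a layout
layout_voxel_indices <- function(grid, layout) {
  xs <- grid_axis(grid, 1); ys <- grid_axis(grid, 2)
  idx <- integer(0)
  for (n in seq_len(nrow(layout))) {
    r <- layout$diameter_mm[n] / 2
    ii <- which(abs(xs - layout$center_x[n]) <= r)
    jj <- which(abs(ys - layout$center_y[n]) <= r)
    if (!length(ii) || !length(jj)) next
    d2 <- outer((xs[ii] - layout$center_x[n])^2,
                (ys[jj] - layout$center_y[n])^2, "+")
    sel <- which(d2 <= r^2, arr.ind = TRUE)
    if (!nrow(sel)) next
    k <- layout$plane_index[n]
    idx <- c(idx, (k - 1L) * grid$dims[1] * grid$dims[2] +
               (jj[sel[, 2]] - 1L) * grid$dims[1] + ii[sel[, 1]])
  }
  unique(idx)
}

#' Background mean and standard deviation
#'
#' Computes the background activity concentration and its standard deviation
#' over the union of all voxels (centers) inside any ROI disc of the layout.
#' By default the SD is the voxelwise sample SD over the union (the layout is
#' treated as one background VOI); `method = "roi_means"` instead returns the
#' SD of the per-ROI means.
#'
#' @param vol An [activity_volume()].
#' @param layout An `roi_layout` from [nema_background_layout()].
#' @param method `"voxelwise"` (default) or `"roi_means"`.
#' @return List with `c_bgr` (kBq/mL), `sd_bgr` (kBq/mL) and `n_voxels`.
#' @export
background_stats <- function(vol, layout, method = c("voxelwise", "roi_means")) {
  method <- match.arg(method)
  if (nrow(layout) == 0) stop("empty ROI layout")
  idx <- layout_voxel_indices(vol$grid, layout)
  if (length(idx) == 0) stop("background ROI union contains no voxels")
  vals <- vol$values[idx]
  if (method == "voxelwise") {
    list(c_bgr = mean(vals), sd_bgr = sd_pop(vals), n_voxels = length(idx))
  } else {
    means <- vapply(seq_len(nrow(layout)), function(n) {
      sub <- layout[n, , drop = FALSE]
      mean(vol$values[layout_voxel_indices(vol$grid, sub)])
    }, 0)
    list(c_bgr = mean(means), sd_bgr = sd_pop(means), n_voxels = length(idx))
  }
}

# population standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
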