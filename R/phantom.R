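#' Spherical phantom insert
#'
#' @param center_mm World coordinates (mm) of the sphere center.
#' @param diameter_mm Sphere diameter (mm), > 0.
#' @param activity_kbq_ml Activity concentration (kBq/mL), >= 0.
#' @param label Text label.
#' @return Object of class `sphere_insert`.
#' @export
sphere_insert <- function(center_mm, diameter_mm, activity_kbq_ml, label = "") {
  if (!is.numeric(diameter_mm) || diameter_mm <= 0)
    stop("sphere diameter must be > 0")
  if (activity_kbq_ml < 0) stop("sphere activity concentration must be >= 0")
  structure(list(center = as.numeric(center_mm), diameter = diameter_mm,
                 activity_conc = activity_kbq_ml, label = as.character(label)),
            class = "sphere_insert")
}

#' Cylindrical density-tube region
#'
#' A tube of given CT density inside the torso, non-radioactive by default.
#' The tube axis is a line segment in world coordinates. Density affects only
#' the label and the optional per-region `noise_scale`; no attenuation or
#' scatter physics is modelled.
#'
#' @param p0_mm,p1_mm Axis segment endpoints (mm).
#' @param diameter_mm Tube diameter (mm).
#' @param nominal_density_hu Nominal CT density (HU), e.g. -800, 500, 1000.
#' @param activity_kbq_ml Tube fill activity concentration (kBq/mL; 0 = cold).
#' @param noise_scale Unitless noise multiplier for the region (default 1).
#' @param label Text label.
#' @return Object of class `tube_region`.
#' @export
tube_region <- function(p0_mm, p1_mm, diameter_mm, nominal_density_hu,
                        activity_kbq_ml = 0, noise_scale = 1, label = "") {
  if (diameter_mm <= 0) stop("tube diameter must be > 0")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  structure(list(p0 = as.numeric(p0_mm), p1 = as.numeric(p1_mm),
                 diameter = diameter_mm, nominal_density_hu = nominal_density_hu,
                 activity_conc = activity_kbq_ml, noise_scale = noise_scale,
                 label = as.character(label)),
            class = "tube_region")
}

#' Axial line source
#'
#' A thin tube running parallel to the scanner axis at a given transaxial
#' offset, used for spatial-resolution measurement.
#'
#' @param transaxial_offset_mm Distance (mm) from the central axis (>= 0).
#' @param inner_diameter_mm Inner diameter (mm), default 0.5.
#' @param activity_kbq_ml Fill activity concentration (kBq/mL).
#' @param length_mm Axial length (mm).
#' @return Object of class `line_source`.
#' @export
line_source <- function(transaxial_offset_mm, inner_diameter_mm = 0.5,
                        activity_kbq_ml = 7100, length_mm = 180) {
  if (inner_diameter_mm <= 0) stop("line inner diameter must be > 0")
  if (transaxial_offset_mm < 0) stop("transaxial offset must be >= 0")
  structure(list(offset = transaxial_offset_mm, diameter = inner_diameter_mm,
                 activity_conc = activity_kbq_ml, length = length_mm),
            class = "line_source")
}

#' Declarative phantom specification
#'
#' Torso-approximating body (elliptical cylinder centered on the world
#' origin), a uniform warm background, and lists of sphere inserts, density
#' tubes and line sources. All geometry is in mm world coordinates.
#'
#' @param name Phantom id.
#' @param body List with `semi_axes` (length-2, mm), `length` (mm), and
#'   optionally `center` (default origin).
#' @param background_kbq_ml Background activity concentration (kBq/mL).
#' @param inserts List of [sphere_insert()].
#' @param tubes List of [tube_region()].
#' @param lines List of [line_source()].
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(name, body, background_kbq_ml = 0,
                         inserts = list(), tubes = list(), lines = list()) {
  if (background_kbq_ml < 0) stop("background concentration must be >= 0")
  if (is.null(body$center)) body$center <- c(0, 0, 0)
  stopifnot(length(body$semi_axes) == 2, body$length > 0,
            all(body$semi_axes > 0))
  spec <- structure(list(name = name, body = body,
                         background_conc = background_kbq_ml,
                         inserts = inserts, tubes = tubes, lines = lines),
                    class = "phantom_spec")
  for (s in inserts) {
    if (!sphere_inside_body(s, body))
      stop(sprintf("insert '%s' does not lie fully inside the body", s$label))
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> '%s': background %.3g kBq/mL, %d spheres, %d tubes, %d lines\n",
              x$name, x$background_conc, length(x$inserts), length(x$tubes),
              length(x$lines)))
  invisible(x)
}

# conservative containment test: sphere inside elliptical cylinder
sphere_inside_body <- function(s, body) {
  r <- s$diameter / 2
  c_rel <- s$center - body$center
  a <- body$semi_axes[1] - r
  b <- body$semi_axes[2] - r
  if (a <= 0 || b <= 0) return(FALSE)
  in_plane <- (c_rel[1] / a)^2 + (c_rel[2] / b)^2 <= 1
  in_axial <- abs(c_rel[3]) + r <= body$length / 2
  in_plane && in_axial
}

preset_path <- function(file) {
  p <- system.file("extdata", "presets", file, package = "petiq")
  if (p == "") {
    # during development (package loaded with load_all)
    p <- file.path("inst", "extdata", "presets", file)
  }
  if (!file.exists(p)) stop("preset file not found: ", file)
  p
}

#' Named phantom presets
#'
#' Builds one of the three study phantoms from its YAML definition shipped
#' with the package:
#' \describe{
#'   \item{`soft_tissue`}{Torso with six hot spheres (6.5-28.0 mm diameter) at
#'     15 kBq/mL on a 57.2-mm ring in a 3 kBq/mL background (SBR 5:1).}
#'   \item{`bone_lung`}{Torso with three cold density tubes (-800, 500,
#'     1000 HU), each containing an 8.5-mm and a 19.4-mm hot sphere at
#'     15 kBq/mL; warm 3 kBq/mL background outside the tubes.}
#'   \item{`resolution`}{Non-radioactive torso with two 0.5-mm line sources at
#'     10 mm and 100 mm transaxial offset, 7.1 MBq/mL fill.}
#' }
#'
#' @param name Preset name.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("soft_tissue", "bone_lung", "resolution")) {
  name <- match.arg(name)
  y <- yaml::read_yaml(preset_path(paste0(name, ".yaml")))
  body <- list(semi_axes = c(y$body$semi_axis_x_mm, y$body$semi_axis_y_mm),
               length = y$body$length_mm)
  inserts <- list(); tubes <- list(); lines <- list()
  ring_r <- y$sphere_ring_radius_mm
  for (ins in y$inserts %||% list()) {
    th <- ins$angle_deg * pi / 180
    inserts[[length(inserts) + 1L]] <- sphere_insert(
      center_mm = c(ring_r * cos(th), ring_r * sin(th), 0),
      diameter_mm = ins$diameter_mm,
      activity_kbq_ml = ins$activity_kbq_ml,
      label = ins$label)
  }
  for (tb in y$tubes %||% list()) {
    hl <- tb$length_mm / 2
    tube <- tube_region(p0_mm = c(tb$center_x_mm, tb$center_y_mm, -hl),
                        p1_mm = c(tb$center_x_mm, tb$center_y_mm, hl),
                        diameter_mm = tb$diameter_mm,
                        nominal_density_hu = tb$density_hu,
                        activity_kbq_ml = tb$activity_kbq_ml %||% 0,
                        noise_scale = tb$noise_scale %||% 1,
                        label = tb$label)
    tubes[[length(tubes) + 1L]] <- tube
    for (sp in y$tube_spheres %||% list()) {
      s <- sphere_insert(
        center_mm = c(tb$center_x_mm, tb$center_y_mm, sp$z_mm),
        diameter_mm = sp$diameter_mm,
        activity_kbq_ml = sp$activity_kbq_ml,
        label = sprintf("%.1fmm@%s", sp$diameter_mm, tb$label))
      if (sqrt(sum((s$center[1:2] - tube$p0[1:2])^2)) + s$diameter / 2 >
          tube$diameter / 2)
        stop("tube sphere does not fit inside tube ", tb$label)
      inserts[[length(inserts) + 1L]] <- s
    }
  }
  for (ln in y$lines %||% list()) {
    lines[[length(lines) + 1L]] <- line_source(
      transaxial_offset_mm = ln$transaxial_offset_mm,
      inner_diameter_mm = ln$inner_diameter_mm,
      activity_kbq_ml = ln$activity_kbq_ml,
      length_mm = y$line_length_mm %||% y$body$length_mm)
  }
  phantom_spec(name, body, y$background_kbq_ml, inserts, tubes, lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
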