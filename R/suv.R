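#' Standardised uptake value
#'
#' `SUV = C[kBq/mL] * body_mass[g] / injected_activity[kBq]`, using the
#' 1 g/mL tissue-density convention. No decay correction is applied (frames
#' are treated as coeval).
#'
#' @param concentration_kbq_ml Tissue activity concentration (kBq/mL), >= 0.
#' @param injected_activity_mbq Administered activity (MBq), > 0.
#' @param body_mass_kg Patient mass (kg), > 0.
#' @return Unitless SUV.
#' @export
compute_suv <- function(concentration_kbq_ml, injected_activity_mbq,
                        body_mass_kg) {
  if (any(concentration_kbq_ml < 0)) stop("concentration must be >= 0")
  if (any(injected_activity_mbq <= 0) || any(body_mass_kg <= 0))
    stop("injected activity and body mass must be > 0")
  concentration_kbq_ml * (body_mass_kg * 1000) / (injected_activity_mbq * 1000)
}

#' Normalise a concentration to the reference injection protocol
#'
#' SUV-preserving rescaling of a measured activity concentration to the
#' guideline reference injection (default 3 MBq/kg into a 70-kg patient):
#' `c * ref_activity_per_kg / (actual_activity / actual_mass)`. The SUV
#' computed before and after normalisation is identical by construction.
#'
#' @param c_kbq_ml Measured concentration (kBq/mL).
#' @param actual_activity_mbq Administered activity (MBq), > 0.
#' @param actual_mass_kg Patient mass (kg), > 0.
#' @param ref_activity_per_kg Reference dose (MBq/kg), default 3.
#' @param ref_mass_kg Reference patient mass (kg), default 70 (kept for
#'   protocol bookkeeping; the rescaling depends only on the per-kg dose).
#' @return Normalised concentration (kBq/mL).
#' @export
normalize_concentration_to_reference_patient <- function(c_kbq_ml,
    actual_activity_mbq, actual_mass_kg, ref_activity_per_kg = 3,
    ref_mass_kg = 70) {
  if (any(actual_activity_mbq <= 0) || any(actual_mass_kg <= 0) ||
      ref_activity_per_kg <= 0 || ref_mass_kg <= 0)
    stop("all activities and masses must be > 0")
  c_kbq_ml * ref_activity_per_kg / (actual_activity_mbq / actual_mass_kg)
}

#' Continuous-bed-motion speed equivalent
#'
#' Converts a per-bed-position acquisition time into the equivalent
#' continuous-bed-motion table speed:
#' `speed = axial_fov * (1 - overlap) / t_bed`. The default 50% bed overlap
#' is a package assumption surfaced here and in the configuration.
#'
#' @param t_bed_s Acquisition time per bed position (s), > 0.
#' @param axial_fov_mm Axial field of view (mm), default 263.
#' @param bed_overlap_fraction Bed overlap fraction in [0, 1), default 0.5.
#' @return Speed in mm/s.
#' @export
cbm_speed_equivalent <- function(t_bed_s, axial_fov_mm = 263,
                                 bed_overlap_fraction = 0.5) {
  if (any(t_bed_s <= 0)) stop("t_bed_s must be > 0")
  if (bed_overlap_fraction < 0 || bed_overlap_fraction >= 1)
    stop("bed_overlap_fraction must be in [0, 1)")
  axial_fov_mm * (1 - bed_overlap_fraction) / t_bed_s
}
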