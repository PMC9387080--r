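#' Contrast-to-noise ratio
#'
#' `CNR = (C_avg - C_bgr) / SD_bgr`, where `C_avg` is the sphere mean in the
#' matched-diameter VOI and the background terms come from the background
#' VOI. May be negative for cold lesions.
#'
#' @param c_avg Sphere mean concentration (kBq/mL).
#' @param c_bgr Background mean concentration (kBq/mL).
#' @param sd_bgr Background standard deviation (kBq/mL), > 0.
#' @return Unitless CNR.
#' @export
compute_cnr <- function(c_avg, c_bgr, sd_bgr) {
  if (any(sd_bgr <= 0)) stop("sd_bgr must be > 0 (degenerate noise)")
  (c_avg - c_bgr) / sd_bgr
}

#' Activity concentration ratio
#'
#' `ACR = C / C_ref` against the long-reference frame; used for both the
#' maximum (ACR_max) and peak (ACR_peak) variants.
#'
#' @param c Concentration at the test acquisition time (kBq/mL).
#' @param c_ref Concentration in the reference frame (kBq/mL), > 0.
#' @return Unitless ratio.
#' @export
compute_acr <- function(c, c_ref) {
  if (any(c_ref <= 0)) stop("reference concentration must be > 0")
  c / c_ref
}

#' Acceptance criteria for detectability and quantification
#'
#' @param cnr_threshold Rose visibility threshold (default 5).
#' @param deviation_band Acceptable fractional deviation of ACR from 1
#'   (default 0.20).
#' @param inclusive Whether the boundaries count as acceptable (default TRUE,
#'   matching "CNR >= 5" and "+/- 20%").
#' @return Object of class `acceptance_criteria`.
#' @export
acceptance_criteria <- function(cnr_threshold = 5, deviation_band = 0.20,
                                inclusive = TRUE) {
  if (cnr_threshold <= 0) stop("cnr_threshold must be > 0")
  if (deviation_band <= 0 || deviation_band >= 1)
    stop("deviation_band must be in (0, 1)")
  structure(list(cnr_threshold = cnr_threshold,
                 deviation_band = deviation_band, inclusive = inclusive),
            class = "acceptance_criteria")
}

#' Measure a simulated time series
#'
#' For every sphere insert and every frame (including the reference) this
#' extracts `c_avg` (matched-diameter VOI mean), `c_max` (maximum within the
#' sphere boundary) and `c_peak` (1-mL sphere at the insert center), plus
#' background mean/SD from an ROI layout when one is supplied, and computes
#' CNR and the ACRs against the reference frame.
#'
#' @param sim A `time_series_sim` from [simulate_time_series()].
#' @param layout Optional `roi_layout` for background noise (soft-tissue
#'   style analysis); without it CNR columns are `NA`.
#' @return A `time_series_table` data frame with one row per (sphere, time);
#'   reference rows carry `is_reference = TRUE` and ACR exactly 1.
#' @export
measure_time_series <- function(sim, layout = NULL) {
  spec <- sim$spec
  grid <- sim$grid
  bg_idx <- if (!is.null(layout)) layout_voxel_indices(grid, layout)
  rows <- list()
  t_ref <- sim$acq$reference_time_s
  for (vol in sim$volumes) {
    t_s <- vol$meta$t_s
    bg <- if (!is.null(bg_idx)) {
      v <- vol$values[bg_idx]
      list(c_bgr = mean(v), sd_bgr = sd_pop(v))
    } else list(c_bgr = NA_real_, sd_bgr = NA_real_)
    for (s in spec$inserts) {
      voi <- spherical_voi(s$center, s$diameter)
      rows[[length(rows) + 1L]] <- data.frame(
        sphere_label = s$label, t_s = t_s,
        c_avg = voi_mean(vol, voi), c_max = voi_max(vol, voi),
        c_peak = peak_voi_value(vol, s$center),
        c_bgr = bg$c_bgr, sd_bgr = bg$sd_bgr,
        is_reference = (t_s == t_ref))
    }
  }
  tab <- do.call(rbind, rows)
  tab$cnr <- ifelse(is.na(tab$sd_bgr), NA_real_,
                    (tab$c_avg - tab$c_bgr) / tab$sd_bgr)
  ref <- tab[tab$is_reference, c("sphere_label", "c_max", "c_peak")]
  names(ref) <- c("sphere_label", "c_max_ref", "c_peak_ref")
  tab <- merge(tab, ref, by = "sphere_label", sort = FALSE)
  tab$acr_max <- compute_acr(tab$c_max, tab$c_max_ref)
  tab$acr_peak <- compute_acr(tab$c_peak, tab$c_peak_ref)
  tab <- tab[order(tab$sphere_label, tab$t_s), ]
  rownames(tab) <- NULL
  class(tab) <- c("time_series_table", "data.frame")
  tab
}

#' Apply the Rose and deviation-band acceptance criteria
#'
#' Fills the logical flag columns: `visible` iff `cnr >= cnr_threshold` and
#' `quant_ok_max` / `quant_ok_peak` iff `|acr - 1| <= deviation_band`
#' (boundaries inclusive by default). Idempotent and rowwise.
#'
#' @param table A `time_series_table` from [measure_time_series()].
#' @param criteria An [acceptance_criteria()].
#' @return The table with flag columns filled.
#' @export
evaluate_acceptance <- function(table, criteria = acceptance_criteria()) {
  need <- c("cnr", "acr_max", "acr_peak")
  if (!all(need %in% names(table)))
    stop("table is missing columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  cmp_ge <- if (criteria$inclusive) `>=` else `>`
  cmp_le <- if (criteria$inclusive) `<=` else `<`
  table$visible <- cmp_ge(table$cnr, criteria$cnr_threshold)
  table$quant_ok_max <- cmp_le(abs(table$acr_max - 1), criteria$deviation_band)
  table$quant_ok_peak <- cmp_le(abs(table$acr_peak - 1), criteria$deviation_band)
  table
}

#' Minimal acceptable acquisition time
#'
#' Smallest grid time at which the given flag holds and keeps holding at
#' every longer grid time (`rule = "sustained"`, the default, which guards
#' against non-monotone noise flapping), or the first passing time
#' (`rule = "first"`). Reference rows are excluded.
#'
#' @param table An evaluated `time_series_table`.
#' @param sphere_label Sphere to query.
#' @param flag_column One of `"visible"`, `"quant_ok_max"`, `"quant_ok_peak"`.
#' @param rule `"sustained"` or `"first"`.
#' @return Time in seconds, or `NA` if the flag is never satisfied.
#' @export
minimal_acceptable_time <- function(table, sphere_label, flag_column,
                                    rule = c("sustained", "first")) {
  rule <- match.arg(rule)
  if (!flag_column %in% names(table))
    stop("unknown flag column: ", flag_column)
  sub <- table[table$sphere_label == sphere_label & !table$is_reference, ]
  if (nrow(sub) == 0) stop("unknown sphere label: ", sphere_label)
  sub <- sub[order(sub$t_s), ]
  flags <- sub[[flag_column]]
  if (anyNA(flags)) stop("flag column contains NA; evaluate acceptance first")
  ok <- if (rule == "sustained") rev(cumprod(rev(flags))) > 0 else flags
  if (!any(ok)) return(NA_real_)
  sub$t_s[which(ok)[1]]
}
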