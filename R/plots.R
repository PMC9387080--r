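#' Plot CNR as a function of acquisition time
#'
#' One line per sphere with a dashed horizontal line at the Rose threshold.
#' Requires ggplot2.
#'
#' @param table A `time_series_table`.
#' @param cnr_threshold Threshold line, default 5.
#' @return A ggplot object.
#' @export
plot_cnr_time <- function(table, cnr_threshold = 5) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- table[!table$is_reference & !is.na(table$cnr), ]
  ggplot2::ggplot(d, ggplot2::aes(x = t_s, y = cnr,
                                  colour = sphere_label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = cnr_threshold, linetype = "dashed") +
    ggplot2::labs(x = "acquisition time (s)", y = "CNR",
                  colour = "sphere") +
    ggplot2::theme_minimal()
}

#' Plot activity concentration ratios with the acceptance band
#'
#' @param table A `time_series_table`.
#' @param which `"acr_max"` or `"acr_peak"`.
#' @param band Acceptance band half-width, default 0.2.
#' @return A ggplot object.
#' @export
plot_acr_time <- function(table, which = c("acr_max", "acr_peak"),
                          band = 0.2) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  which <- match.arg(which)
  d <- table[!table$is_reference, ]
  d$acr <- d[[which]]
  ggplot2::ggplot(d, ggplot2::aes(x = t_s, y = acr,
                                  colour = sphere_label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(1 - band, 1 + band),
                        linetype = "dashed") +
    ggplot2::labs(x = "acquisition time (s)", y = which,
                  colour = "sphere") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot for a paired-lesion table
#'
#' @param pairs A `paired_measurements` data frame.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pairs) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ba <- bland_altman(pairs)
  d <- data.frame(m = (pairs$value_full + pairs$value_reduced) / 2,
                  d = pairs$value_reduced - pairs$value_full)
  ggplot2::ggplot(d, ggplot2::aes(x = m, y = d)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = ba$loa, linetype = "dashed") +
    ggplot2::labs(x = "mean of paired values", y = "reduced - full") +
    ggplot2::theme_minimal()
}
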