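# Figures: bias vs reference T1 on a log axis with confidence-interval bars.

#' Plot group-mean normalized error against reference T1
#'
#' The study's bias figure: per-vendor mean normalized error per sphere (in
#' percent) against the NMR reference T1 on a log axis, with 95% confidence
#' interval error bars; one panel per modality when several are present.
#'
#' @param records Bias-record tibble, or the `summary` tibble of a pipeline
#'   result (detected by its `mean_error_pct` column).
#' @param group_by Grouping column (default "vendor").
#' @return A ggplot object.
#' @export
plot_bias <- function(records, group_by = "vendor") {
  smry <- if ("mean_error_pct" %in% names(records)) {
    records
  } else if ("modality" %in% names(records)) {
    records |>
      dplyr::group_by(.data$modality) |>
      dplyr::group_modify(~ group_summary(.x, group_by = group_by)) |>
      dplyr::ungroup()
  } else {
    group_summary(records, group_by = group_by)
  }
  p <- ggplot2::ggplot(
    smry,
    ggplot2::aes(x = .data$t1_nmr_ms, y = .data$mean_error_pct,
                 colour = .data[[group_by]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      width = 0.03, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(T[1*",NMR"]~(ms)),
                  y = "Normalized error (%)", colour = group_by) +
    ggplot2::theme_minimal()
  if ("modality" %in% names(smry) &&
      dplyr::n_distinct(smry$modality) > 1) {
    p <- p + ggplot2::facet_wrap(~modality, labeller = ggplot2::label_both)
  }
  p
}

#' @export
autoplot.t1_pipeline_result <- function(object, ...) {
  plot_bias(object$summary)
}

#' @export
autoplot.image_series <- function(object, index = 1L, ...) {
  img <- object$images[[index]]
  n <- nrow(img)
  coords <- pixel_coords_mm(n, object$protocol$pixel_mm)
  df <- tibble::tibble(
    x = rep(coords, each = n),
    y = rep(coords, times = n),
    signal = as.vector(img)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(
      x = "x (mm)", y = "y (mm)",
      title = paste0(toupper(object$protocol$modality), " image at ",
                     object$series_values[index],
                     if (object$protocol$modality == "ir") " ms" else " deg")) +
    ggplot2::theme_minimal()
}
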