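#' Plot quantified ROIs for one image
#'
#' Draws each ROI at its centroid, sized by area and coloured by its
#' background-subtracted mean intensity — a quick visual check that the
#' segmentation picked up the expected nuclei. The y axis is flipped so the
#' plot matches image orientation (origin top-left).
#'
#' @param object An `fq_quant` table from [quantify_image()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fq_quant <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y,
                 size = .data$area_px, colour = .data$mean_corrected)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = attr(object, "image_id"),
      subtitle = sprintf("%d ROIs, background %.2f", nrow(object),
                         attr(object, "mean_bg")),
      x = "x (px)", y = "y (px)",
      colour = "corrected\nmean", size = "area (px²)"
    )
}

#' @rdname agreement
#' @param object An `fq_agreement` object.
#' @param ... Unused.
#' @export
autoplot.fq_agreement <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "blue", linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("Agreement: R² = %.3f", object$r_squared),
      subtitle = sprintf("b = %.3f a + %.3f (red: identity)",
                         object$slope, object$intercept),
      x = "reading a", y = "reading b"
    )
}

#' Plot per-group intensity distributions
#'
#' Jittered per-image values with group mean and SD overlaid, the standard
#' presentation for small-n group comparisons of immunofluorescence
#' intensity.
#'
#' @inheritParams group_summaries
#' @return A ggplot object.
#' @export
plot_group_values <- function(data, value = mean_corrected_mean,
                              group = group) {
  smry <- group_summaries(data, {{ value }}, {{ group }})
  ggplot2::ggplot(data, ggplot2::aes(x = {{ group }}, y = {{ value }})) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.7) +
    ggplot2::geom_pointrange(
      data = smry,
      ggplot2::aes(x = .data$group, y = .data$mean,
                   ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      colour = "red", inherit.aes = FALSE
    ) +
    ggplot2::labs(x = NULL, y = "image mean corrected intensity")
}
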