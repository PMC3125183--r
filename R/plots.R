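#' Island map for a prediction
#'
#' Draws each predicted island as a horizontal segment along its
#' chromosome, coloured by GC content, with segment thickness constant —
#' a quick visual check of island placement and composition.
#'
#' @param object A `cpg_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpg_prediction <- function(object, ...) {
  isl <- object$islands
  ggplot2::ggplot(isl) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$chrom, yend = .data$chrom, colour = .data$gc
      ),
      linewidth = 4
    ) +
    ggplot2::scale_colour_viridis_c(name = "GC") +
    ggplot2::labs(
      x = "position (bp)", y = NULL,
      title = sprintf("%d predicted CpG island(s)", nrow(isl))
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param points Tibble from [roc_points()].
#' @return A ggplot object with the chance diagonal for reference.
#' @export
plot_roc <- function(points) {
  ggplot2::ggplot(points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Metric bars for an evaluation
#'
#' @param object A `cpg_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpg_evaluation <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(toupper(.data$metric), .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(NA, 1) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}
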