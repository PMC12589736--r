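#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: the
#' segmentation mask over the image, the feature-selection score trace,
#' and a per-class metric panel.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name histofuse-plots
NULL

raster_df <- function(px) {
  if (length(dim(px)) == 3L) px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  tibble::tibble(
    row = rep(seq_len(nrow(px)), times = ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    value = as.vector(px)
  )
}

#' @rdname histofuse-plots
#' @param img Optional [raster_image()] to draw under the mask contour.
#' @export
autoplot.segmentation_result <- function(object, img = NULL, ...) {
  df <- raster_df(if (is.null(img)) matrix(as.numeric(object$mask), nrow(object$mask))
                  else img$pixels)
  df$mask <- as.vector(object$mask) * 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$mask), breaks = 0.5,
                          colour = "red", linewidth = 0.4) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Active-contour segmentation", x = NULL, y = NULL)
}

#' @rdname histofuse-plots
#' @export
autoplot.selection_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$iteration, .data$best_score)) +
    ggplot2::geom_step() +
    ggplot2::labs(title = "Ant-colony feature selection",
                  subtitle = sprintf("%d features retained, best objective %.3f",
                                     length(object$best_subset), object$best_score),
                  x = "iteration", y = "best objective") +
    ggplot2::theme_minimal()
}

#' @rdname histofuse-plots
#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(tibble::as_tibble(object), .data$class != "macro"),
    cols = c("auc", "sensitivity", "accuracy", "precision", "f1", "specificity"),
    names_to = "metric", values_to = "percent"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(min(90, min(long$percent, na.rm = TRUE)), 100)) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
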