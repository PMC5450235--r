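#' Probability-contour plot of a trained targeting model
#'
#' Classifier map in the (tail charge, TMD GRAVY) plane: the background
#' shows the highest-probability class on a lattice, contour lines mark
#' the indicated probability levels for each class, and the training
#' points (or any supplied feature table) are overlaid.
#'
#' @param object A [ta_train()] model.
#' @param charge_range,gravy_range,step Lattice, see [probability_grid()].
#' @param data Feature table of points to overlay; defaults to the
#'   training set stored in the model. Use `NULL` to omit points.
#' @param levels Probability contour levels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ta_svm <- function(object, charge_range = c(-2, 10),
                            gravy_range = c(0, 4), step = 0.1,
                            data = object$training, levels = c(0.5, 0.75),
                            ...) {
  grid <- probability_grid(object, charge_range, gravy_range, step)
  long <- tidyr::pivot_longer(grid, dplyr::all_of(c("p_PO", "p_MITO", "p_ER")),
                              names_to = "class", values_to = "p")
  long$class <- sub("^p_", "", long$class)
  pal <- c(PO = "#4daf4a", MITO = "#377eb8", ER = "#f4a582")
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$tail_charge,
                                          y = .data$tmd_gravy)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$predicted), alpha = 0.25) +
    ggplot2::geom_contour(
      data = long,
      ggplot2::aes(z = .data$p, colour = .data$class),
      breaks = levels, linewidth = 0.4
    ) +
    ggplot2::scale_fill_manual(values = pal, name = "predicted") +
    ggplot2::scale_colour_manual(values = pal, name = "class") +
    ggplot2::labs(x = "net tail charge (pH 7)", y = "TMD GRAVY") +
    ggplot2::theme_minimal()
  if (!is.null(data) && nrow(data) > 0) {
    pts <- as_tibble(data)
    if (!"label" %in% names(pts)) pts$label <- "unlabelled"
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$tail_charge, y = .data$tmd_gravy,
                   shape = .data$label),
      size = 2
    )
  }
  p
}

#' Box-and-whisker plot of a group comparison
#'
#' Boxes span the 25th-75th percentiles, the median is marked and the
#' whiskers span the sample range, with the per-group points overlaid.
#'
#' @param object A [compare_groups()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ta_group_comparison <- function(object, ...) {
  df <- object$data
  df$group <- factor(df$group, levels = object$summaries$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(coef = Inf, outlier.shape = NA, width = 0.6) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6, size = 1.5) +
    ggplot2::labs(x = NULL, y = object$feature) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
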