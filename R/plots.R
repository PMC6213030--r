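#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum (NMR convention: ppm decreasing)
#' @param object An `nmr_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nmr_spectrum
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = expression(delta ~ "(ppm)"), y = "intensity (a.u.)",
      title = sample_id(object)
    ) +
    ggplot2::theme_minimal()
}

score_plot <- function(scores_tbl, xcol, ycol, xlab, ylab) {
  p <- ggplot2::ggplot(
    scores_tbl,
    ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]])
  )
  if ("group" %in% names(scores_tbl)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = xlab, y = ylab) + ggplot2::theme_minimal()
}

#' PCA score plot
#' @param object An `nmr_pca`.
#' @param components Two component indices (default 1:2).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nmr_pca
#' @export
autoplot.nmr_pca <- function(object, components = 1:2, ...) {
  ev <- object$explained_variance_fraction
  cols <- paste0("PC", components)
  score_plot(
    tidy(object), cols[1], cols[2],
    sprintf("%s (%.1f%%)", cols[1], 100 * ev[components[1]]),
    sprintf("%s (%.1f%%)", cols[2], 100 * ev[components[2]])
  )
}

#' PLS-DA score plot
#' @param object An `nmr_plsda`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nmr_plsda
#' @export
autoplot.nmr_plsda <- function(object, ...) {
  score_plot(tidy(object), "LV1", "LV2", "LV1", "LV2")
}

#' Correlation-colored loading profile plot
#'
#' Back-scaled loadings as a pseudo-spectrum (positive = higher in the
#' terrestrial group), colored by the absolute correlation with class
#' membership.
#'
#' @param object A [loading_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot loading_profile
#' @export
autoplot.loading_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$bin, y = .data$loading, color = .data$abs_r
  )) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$bin, yend = 0)) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_color_gradient(low = "blue", high = "red", limits = c(0, 1)) +
    ggplot2::labs(
      x = expression(delta ~ "(ppm)"), y = "back-scaled loading",
      color = "|r|"
    ) +
    ggplot2::theme_minimal()
}

#' STOCSY trace plot
#'
#' Covariance pseudo-spectrum colored by the correlation to the driver.
#'
#' @param object A [stocsy()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stocsy_result
#' @export
autoplot.stocsy_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$bin, y = .data$covariance, color = abs(.data$correlation)
  )) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_color_gradient(low = "blue", high = "red", limits = c(0, 1)) +
    ggplot2::labs(
      x = expression(delta ~ "(ppm)"), y = "covariance", color = "|r|",
      title = sprintf("STOCSY, driver %.3f ppm", attr(object, "driver"))
    ) +
    ggplot2::theme_minimal()
}

#' Fold-change plot of univariate results
#'
#' log2 fold change (marine vs terrestrial) per metabolite, colored by
#' Benjamini-Hochberg-adjusted p-value, with dashed guide lines at 20%
#' (FC 0.8, 1.2) and 100% (FC 0.5, 2.0) variation.
#'
#' @param result A [univariate_analysis()] result.
#' @return A ggplot.
#' @export
plot_fold_change <- function(result) {
  guides <- log2(c(0.8, 1.2, 0.5, 2.0))
  ggplot2::ggplot(result, ggplot2::aes(
    x = .data$metabolite, y = .data$log2_fold_change,
    color = .data$p_adjusted
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(
      yintercept = guides[1:2], linetype = "dashed", color = "blue"
    ) +
    ggplot2::geom_hline(
      yintercept = guides[3:4], linetype = "dashed", color = "red"
    ) +
    ggplot2::geom_hline(yintercept = 0, color = "grey50") +
    ggplot2::labs(
      x = NULL, y = expression(log[2] ~ "fold change (marine/terrestrial)"),
      color = "adj. p"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Correlation network plot
#'
#' Nodes colored by log2 fold change (bluish = lower in marine, reddish =
#' higher), warm/cool edges for positive/negative correlations, edge
#' width scaled by |r|.
#'
#' @param object A `metab_network`.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot metab_network
#' @export
autoplot.metab_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  layout <- withr::with_seed(
    seed, igraph::layout_with_fr(g)
  )
  nodes <- dplyr::mutate(object$nodes,
    x = layout[, 1], y = layout[, 2]
  )
  edges <- dplyr::left_join(
    dplyr::left_join(
      object$edges,
      dplyr::select(nodes, from = "metabolite", x0 = "x", y0 = "y"),
      by = "from"
    ),
    dplyr::select(nodes, to = "metabolite", x1 = "x", y1 = "y"),
    by = "to"
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        color = .data$sign, linewidth = .data$weight
      ),
      linetype = "dashed"
    ) +
    ggplot2::scale_color_manual(
      values = c(positive = "orangered", negative = "steelblue")
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5), guide = "none") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$log2_fold_change),
      shape = 21, size = 5
    ) +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red", midpoint = 0
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$metabolite),
      size = 2, vjust = -1.5
    ) +
    ggplot2::labs(
      fill = expression(log[2] ~ "FC"), color = "correlation",
      title = if (is.null(object$group)) NULL else
        sprintf("%s network (|r| > %.2f)", object$group, object$threshold)
    ) +
    ggplot2::theme_void()
}
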