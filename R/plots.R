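# ggplot2 displays for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot held-out or resubstitution sex scores
#'
#' Histogram of the male-minus-female score difference `d`, filled by true
#' sex when available, with the decision boundary at zero.
#'
#' @param object A `sex_scores` tibble from [svm_score()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sex_scores <- function(object, ...) {
  p <- if ("true_sex" %in% names(object)) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$d, fill = .data$true_sex))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$d))
  }
  p +
    ggplot2::geom_histogram(bins = 30, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "SVM score difference d (male - female)", y = "fish",
                  fill = "true sex",
                  title = "Fin-color SVM decision values") +
    ggplot2::theme_minimal()
}

#' Plot a CNN training log
#'
#' @param object A `cnn_sexer`.
#' @param ... Unused.
#' @return A ggplot of loss and training accuracy per epoch.
#' @export
autoplot.cnn_sexer <- function(object, ...) {
  lg <- tidyr::pivot_longer(object$training_log, c("loss", "accuracy"),
                            names_to = "metric")
  ggplot2::ggplot(lg, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = "CNN training", x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot LS-means with confidence limits and letter display
#'
#' Renders the treatment-by-sex adjusted means of an intensity or size
#' model as points with confidence intervals, annotated with compact
#' letters (cells sharing a letter do not differ significantly).
#'
#' @param ls An [ls_means()] result.
#' @param ylab Axis label.
#' @return A ggplot.
#' @export
plot_ls_means <- function(ls, ylab = "LS-mean") {
  m <- ls$means
  facs <- intersect(c("group", "sex"), names(m))
  m$cell <- do.call(paste, c(as.list(m[facs]), sep = " "))
  lo <- if ("lower.CL" %in% names(m)) m$lower.CL else m$asymp.LCL
  hi <- if ("upper.CL" %in% names(m)) m$upper.CL else m$asymp.UCL
  m$.lo <- lo; m$.hi <- hi
  ggplot2::ggplot(m, ggplot2::aes(x = .data$cell, y = .data$emmean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$.lo, ymax = .data$.hi)) +
    ggplot2::geom_text(ggplot2::aes(y = .data$.hi, label = .data$letters),
                       vjust = -0.6) +
    ggplot2::labs(x = NULL, y = ylab, title = "Adjusted cell means (Tukey-Kramer letters)") +
    ggplot2::theme_minimal()
}

#' Plot intensity against body size with fitted per-cell curves
#'
#' Scatter of the z intensity against the covariate, with the fitted
#' ANCOVA mean curve per treatment-by-sex cell.
#'
#' @param fit An `ancova_fit`.
#' @param n_grid Points along the covariate axis.
#' @return A ggplot.
#' @export
plot_ancova_curves <- function(fit, n_grid = 50) {
  stopifnot(inherits(fit, "ancova_fit"))
  fr <- fit$frame
  raw <- fr$x1 + fit$center
  grid_x <- seq(min(raw), max(raw), length.out = n_grid)
  lm_at <- ls_means(fit, at = grid_x)
  m <- lm_at$means
  m$cell <- paste(m$group, m$sex)
  fr$cell <- paste(fr$group, fr$sex)
  fr$raw <- raw
  ggplot2::ggplot() +
    ggplot2::geom_point(data = fr, ggplot2::aes(x = .data$raw, y = .data$y,
                                                color = .data$cell), alpha = 0.5) +
    ggplot2::geom_line(data = m, ggplot2::aes(x = .data$at, y = .data$emmean,
                                              color = .data$cell)) +
    ggplot2::labs(x = fit$spec$covariate, y = "color intensity (z)",
                  color = NULL,
                  title = "Fin-color intensity against body size") +
    ggplot2::theme_minimal()
}
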