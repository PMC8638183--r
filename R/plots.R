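#' Four-quadrant plot
#'
#' Scatter of the difference pairs (x, y), coloured by agreement status,
#' with the exclusion-zone square and the 45-degree reference line.
#'
#' @inheritParams classify_trends
#' @return A ggplot object.
#' @export
plot_four_quadrant <- function(diffs, a = 0) {
  d <- classify_trends(diffs, a)
  d$status <- ifelse(d$excluded, "excluded",
                     ifelse(d$agreement, "agreement", "disagreement"))
  rng <- max(abs(c(d$x, d$y, a))) * 1.05
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$status)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(agreement = "#c0392b",
                                            disagreement = "#2980b9",
                                            excluded = "grey60")) +
    ggplot2::coord_equal(xlim = c(-rng, rng), ylim = c(-rng, rng)) +
    ggplot2::labs(x = "difference, reference method",
                  y = "difference, test method", colour = NULL) +
    ggplot2::theme_minimal()
  if (a > 0) {
    p <- p + ggplot2::annotate("rect", xmin = -a, xmax = a, ymin = -a,
                               ymax = a, alpha = 0.15, fill = "grey40")
  }
  p
}

#' @export
autoplot.trend_differences <- function(object, a = 0, ...) {
  plot_four_quadrant(object, a = a)
}

#' @export
autoplot.quadconc_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc_points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sbp_bootstrap <- function(object, ...) {
  est <- object$estimates[!is.na(object$estimates$rate), ]
  rocs <- split(est, est$method)
  pts <- purrr::map_dfr(names(rocs), function(mm) {
    r <- roc_auc(rocs[[mm]]$rate, rocs[[mm]]$label)
    dplyr::mutate(r$roc_points, method = mm)
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
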