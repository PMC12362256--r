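#' Plot a CAT result
#'
#' Histogram of the B permuted R-squared values with the original
#' R-squared as a dashed line — the visual form of the test: a taxon
#' matters when the observed value sits in the right tail of its own
#' permutation distribution.
#'
#' @param object A `cat_result` from [cat_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.cat_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r2_perm)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(xintercept = object$r2_original,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = expression(R^2 ~ "of permuted datasets"), y = "count",
      title = sprintf("CAT: %s (p = %.3g, B = %d)", object$taxon,
                      object$p_value, object$b)
    ) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' PCoA ordination plot
#'
#' Computes principal coordinates from a distance matrix and plots the
#' first two axes, optionally coloured by group — the standard picture of
#' between-group separation in community composition.
#'
#' @param d A distance matrix.
#' @param group Optional per-sample grouping vector.
#' @return A ggplot object.
#' @export
plot_pcoa <- function(d, group = NULL) {
  res <- pcoa(gower_center(d), k = 2)
  co <- res$coordinates
  if (ncol(co) < 2) abort("fewer than two positive PCoA axes")
  rel <- res$eigenvalues / sum(abs(res$eigenvalues))
  df <- tibble::tibble(
    PCo1 = co[, 1], PCo2 = co[, 2],
    group = if (is.null(group)) "all" else as.factor(group)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.95, na.rm = TRUE) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * rel[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * rel[2])
    ) +
    ggplot2::theme_minimal()
}

#' Rejection-rate plot for a calibration/power study
#'
#' @param study Output of [run_calibration_study()].
#' @param alpha Significance level line (default 0.05).
#' @return A ggplot object.
#' @export
plot_power_curve <- function(study, alpha = 0.05) {
  ggplot2::ggplot(study$rates,
                  ggplot2::aes(x = .data$lambda, y = .data$rejection_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$rejection_rate - 1.96 * .data$se),
      ymax = pmin(1, .data$rejection_rate + 1.96 * .data$se)
    )) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::labs(x = expression(lambda ~ "(spike mean)"),
                  y = sprintf("rejection rate at %.2f", alpha)) +
    ggplot2::theme_minimal()
}
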