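# ggplot2 views of the main result types.

#' Diagram-of-states scatter plot
#'
#' Plots proteins in the (f+, f-) plane colored by their five-region
#' classification, with the FCR = 0.25 / 0.35 region boundaries drawn.
#'
#' @param metrics Tibble from [classify_das_pappu()] or
#'   [compose_proteins()].
#' @return A ggplot object.
#' @export
plot_diagram_of_states <- function(metrics) {
  stopifnot(all(c("f_plus", "f_minus", "region_label") %in% names(metrics)))
  boundary <- function(c) tibble(
    f_minus = seq(0, c, length.out = 50),
    f_plus = c - seq(0, c, length.out = 50)
  )
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = .data$f_minus, y = .data$f_plus)) +
    ggplot2::geom_line(data = boundary(0.25), linetype = 2, colour = "grey40") +
    ggplot2::geom_line(data = boundary(0.35), linetype = 2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$region_label), alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "fraction of negative residues (f-)",
      y = "fraction of positive residues (f+)",
      colour = "region"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of contrasts with the origin-fixed fit
#'
#' @param object An `origin_fit` from [origin_regression()] or
#'   [contrast_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.origin_fit <- function(object, ...) {
  df <- tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "OGT contrast (standardized)",
      y = "FOD contrast (standardized)",
      subtitle = sprintf("slope = %.4g, R² = %.3g, p = %.3g",
                         object$slope, object$r_squared, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Aligned disorder tracks for a cluster
#'
#' One smoothed line per cluster member along the alignment columns.
#'
#' @param tracks Tibble from [aligned_profile_table()].
#' @return A ggplot object.
#' @export
plot_disorder_tracks <- function(tracks) {
  stopifnot(all(c("member", "column", "smoothed") %in% names(tracks)))
  ggplot2::ggplot(tracks,
                  ggplot2::aes(x = .data$column, y = .data$smoothed,
                               colour = .data$member)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "alignment column", y = "smoothed disorder score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
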