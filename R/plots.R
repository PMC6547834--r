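#' Plot a fitted learning curve over its score series
#'
#' @param y,x Score series and administration indexes, as passed to
#'   [fit_inverse_curve()].
#' @param fit Optional `learning_curve_fit`; refitted from the series when
#'   omitted.
#' @param ylab Axis label for the outcome measure.
#' @return A ggplot object: observed points, the fitted inverse curve, and
#'   the training endpoint marked at 90% of the plateau.
#' @export
plot_learning_curve <- function(y, x = seq_along(y), fit = NULL,
                                ylab = "score") {
  if (is.null(fit)) fit <- fit_inverse_curve(y, x)
  grid <- seq(min(x), max(x), length.out = 200)
  curve_df <- data.frame(x = grid, y = fit$a - fit$b / grid)
  ep_x <- fit$endpoint - fit$session_offset
  ggplot2::ggplot(data.frame(x = x, y = y), ggplot2::aes(x, y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve_df, colour = "red") +
    ggplot2::annotate("point", x = ep_x, y = fit$a - fit$b / ep_x,
                      shape = 17, size = 3) +
    ggplot2::labs(x = "administration index", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot session effect sizes against the conventional thresholds
#'
#' @param effects Output of [session_effect_sizes()].
#' @return A ggplot object with the 0.2 / 0.5 / 0.8 threshold lines.
#' @export
plot_effect_sizes <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(.data$session, .data$es)) +
    ggplot2::geom_hline(yintercept = c(0.2, 0.5, 0.8), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(colour = "blue") +
    ggplot2::geom_point(colour = "blue") +
    ggplot2::labs(x = "session", y = "effect size") +
    ggplot2::theme_minimal()
}
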