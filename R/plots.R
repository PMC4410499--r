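#' Plot bias curves of a heterogeneity estimator
#'
#' Draws the expectation of the estimator against the number of studies, one
#' panel per true heterogeneity fraction, with a dashed line at the estimand
#' so the vertical gap is the bias.
#'
#' @param curve A tibble from [bias_curve()] (or [i2_expectation()] rows).
#' @return A ggplot object.
#' @examples
#' plot_bias_curve(bias_curve("random", iota2 = c(0.1, 0.5, 0.8), K = seq(4, 40, 2)))
#' @export
plot_bias_curve <- function(curve) {
  required <- c("iota2", "K", "expectation")
  if (!is.data.frame(curve) || !all(required %in% names(curve))) {
    abort_invalid("`curve` must be a bias_curve() tibble with iota2, K, expectation.")
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$K, y = .data$expectation)) +
    ggplot2::geom_hline(
      ggplot2::aes(yintercept = .data$iota2), linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~iota2, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Number of studies K", y = expression(E(I^2)),
      title = "Expectation of the truncated heterogeneity estimator",
      subtitle = "Dashed line: true heterogeneity fraction (gap = bias)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the probability of a zero I-squared estimate under homogeneity
#'
#' The probability that a central chi-square variable falls below its own
#' degrees of freedom: the chance that the naive estimator is negative (and
#' the truncated estimator exactly zero) when there is no heterogeneity.
#' It decreases with `df` but always exceeds one half.
#'
#' @param df Integer vector of degrees of freedom.
#' @return A ggplot object.
#' @examples
#' plot_truncation_probability(1:50)
#' @export
plot_truncation_probability <- function(df = 1:200) {
  if (!is.numeric(df) || any(df < 1) || any(df != round(df))) {
    abort_invalid("`df` must be positive integers.")
  }
  d <- tibble(df = as.integer(df), probability = pchisq(df, df))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$df, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Degrees of freedom (K - 1)", y = expression(P(Q < df)),
      title = "Probability of a zero heterogeneity estimate under homogeneity"
    ) +
    ggplot2::theme_minimal()
}
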