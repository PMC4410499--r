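#' Precision-weighted mean effect
#'
#' The inverse-variance weighted average of the study effects,
#' \eqn{\hat{\bar\beta} = \sum_k \hat\sigma_k^{-2}\hat\beta_k /
#' \sum_k \hat\sigma_k^{-2}}.
#'
#' @param studies A data frame with columns `effect` and `se`
#'   (see [as_study_set()]).
#' @return A single number.
#' @examples
#' weighted_mean(data.frame(effect = c(0, 1), se = c(1, 2)))
#' @export
weighted_mean <- function(studies) {
  studies <- as_study_set(studies)
  w <- 1 / studies$se^2
  sum(w * studies$effect) / sum(w)
}

#' Cochran's Q statistic
#'
#' The precision-weighted sum of squared deviations of the study effects from
#' their weighted mean, \eqn{Q = \sum_k (\hat\beta_k - \hat{\bar\beta})^2 /
#' \hat\sigma_k^2}.  Q is invariant to adding a constant to all effects and to
#' rescaling all effects and standard errors by a common factor.
#'
#' @inheritParams weighted_mean
#' @return A single nonnegative number; 0 exactly when all effects are equal.
#' @examples
#' cochran_q(data.frame(effect = c(0, 1), se = c(1, 1)))
#' @export
cochran_q <- function(studies) {
  studies <- as_study_set(studies)
  wm <- sum(studies$effect / studies$se^2) / sum(1 / studies$se^2)
  sum((studies$effect - wm)^2 / studies$se^2)
}

#' Naive heterogeneity-fraction estimator
#'
#' The moment estimator \eqn{\hat\iota^2 = 1 - df/Q} of the fraction of
#' between-study variance due to heterogeneity.  Unlike the estimand, it can
#' be negative (whenever `Q < df`).  At `Q = 0` the ratio is undefined; the
#' function returns `-Inf` with a warning, which the truncated estimator maps
#' to 0.
#'
#' @param Q Cochran's Q statistic (nonnegative scalar).
#' @param df Degrees of freedom, `K - 1` (positive integer).
#' @return A single number, at most 1.
#' @examples
#' naive_iota2(Q = 12, df = 6)
#' naive_iota2(Q = 3, df = 6) # negative
#' @export
naive_iota2 <- function(Q, df) {
  Q <- check_scalar_number(Q, "Q", min = 0)
  df <- check_count(df, "df", min = 1L)
  if (Q == 0) {
    warn("Q = 0 (all effects identical): the naive estimator is -Inf; I2 is 0.")
    return(-Inf)
  }
  1 - df / Q
}

#' Truncated heterogeneity-fraction estimator
#'
#' Rounds negative values of the naive estimator up to zero:
#' \eqn{I^2 = \max(0, \hat\iota^2)}.  This is the statistic in universal use.
#'
#' @param naive Value of the naive estimator (at most 1; may be `-Inf`).
#' @return A single number in `[0, 1)`.
#' @examples
#' truncated_i2(-0.4)
#' truncated_i2(0.37)
#' @export
truncated_i2 <- function(naive) {
  if (!is.numeric(naive) || length(naive) != 1L || is.na(naive)) {
    abort_invalid("`naive` must be a single number (possibly -Inf).")
  }
  if (naive > 1) {
    abort_invalid("`naive` cannot exceed 1 (it is 1 - df/Q with Q, df > 0).")
  }
  max(0, naive)
}

#' Estimate heterogeneity from study-level data
#'
#' Computes the full set of heterogeneity statistics for one meta-analysis:
#' the precision-weighted mean, Cochran's Q, its degrees of freedom, the naive
#' estimator \eqn{\hat\iota^2 = 1 - df/Q}, and the truncated estimator
#' \eqn{I^2 = \max(0, \hat\iota^2)}.
#'
#' @inheritParams weighted_mean
#' @return An object of class `i2_fit`: a list with elements `studies`
#'   (the validated study-set tibble), `K`, `df`, `weighted_mean`, `Q`,
#'   `naive_iota2`, `I2`.  Use [glance()] for a one-row tibble of the
#'   statistics and [tidy()] for per-study contributions to Q.
#' @examples
#' fit <- estimate_heterogeneity(
#'   data.frame(effect = c(0.1, 0.5, 0.9, 0.2), se = c(0.2, 0.2, 0.3, 0.25))
#' )
#' fit
#' glance(fit)
#' tidy(fit)
#' @export
estimate_heterogeneity <- function(studies) {
  studies <- as_study_set(studies)
  K <- nrow(studies)
  df <- K - 1L
  wm <- weighted_mean(studies)
  Q <- cochran_q(studies)
  naive <- naive_iota2(Q, df)
  structure(
    list(
      studies = studies, K = K, df = df, weighted_mean = wm, Q = Q,
      naive_iota2 = naive, I2 = truncated_i2(naive)
    ),
    class = "i2_fit"
  )
}

#' @export
print.i2_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Heterogeneity of %d studies (df = %d)\n", x$K, x$df))
  cat(sprintf("  weighted mean effect: %s\n", format(x$weighted_mean, digits = digits)))
  cat(sprintf("  Cochran's Q:          %s\n", format(x$Q, digits = digits)))
  cat(sprintf("  naive iota^2:         %s\n", format(x$naive_iota2, digits = digits)))
  cat(sprintf("  I^2:                  %s\n", format(x$I2, digits = digits)))
  if (x$df > 2) {
    b <- expected_i2_closed("homogeneous", 0, x$df)
    cat(sprintf(
      "  If the studies were homogeneous, E(I^2) would still be %.2f at df = %d.\n",
      b, x$df
    ))
  }
  if (x$K <= 7) {
    cat("  Note: with few studies I^2 is imprecise and can be substantially biased;\n")
    cat("  interpret the point estimate cautiously.\n")
  }
  invisible(x)
}

#' Per-study contributions of a heterogeneity fit
#'
#' One row per study: precision weight, deviation from the weighted mean,
#' and contribution to Cochran's Q.
#'
#' @param x An `i2_fit` object from [estimate_heterogeneity()].
#' @param ... Unused; kept for generic consistency.
#' @return A tibble with one row per study.
#' @export
tidy.i2_fit <- function(x, ...) {
  s <- x$studies
  dplyr::mutate(
    s,
    weight = 1 / .data$se^2,
    deviation = .data$effect - x$weighted_mean,
    q_contribution = .data$deviation^2 / .data$se^2
  )
}

#' One-row summary of a heterogeneity fit
#'
#' @inheritParams tidy.i2_fit
#' @return A one-row tibble with `K`, `df`, `weighted_mean`, `Q`,
#'   `naive_iota2`, `I2`.
#' @export
glance.i2_fit <- function(x, ...) {
  tibble(
    K = x$K, df = x$df, weighted_mean = x$weighted_mean, Q = x$Q,
    naive_iota2 = x$naive_iota2, I2 = x$I2
  )
}

#' Bar chart of per-study contributions to Cochran's Q
#'
#' @param object An `i2_fit` object from [estimate_heterogeneity()].
#' @param ... Unused; kept for generic consistency.
#' @return A ggplot object.
#' @export
autoplot.i2_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$study, y = .data$q_contribution)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = NULL, y = "Contribution to Q",
      title = sprintf(
        "Q = %.3g on %d df; I² = %.1f%%",
        object$Q, object$df, 100 * object$I2
      )
    ) +
    ggplot2::theme_minimal()
}
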