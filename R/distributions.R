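# Sampling distribution of Cochran's Q under the three models, in the
# equal-sigma, large-sample regime:
#   homogeneous : Q ~ chi-square(df)
#   random      : (1 - iota2) Q ~ chi-square(df), i.e. Q is a scaled central
#                 chi-square with scale 1/(1 - iota2)
#   fixed       : Q ~ noncentral chi-square(df, lambda),
#                 lambda = K iota2 / (1 - iota2)

#' Noncentrality parameter of Q under the fixed-effects model
#'
#' With a common within-study standard error, the noncentrality parameter of
#' Cochran's Q under the fixed-effects model is
#' \eqn{\lambda = K\,\iota^2/(1-\iota^2)}: zero at homogeneity and strictly
#' increasing in the heterogeneity fraction.
#'
#' @param iota2 True heterogeneity fraction, in `[0, 1)`.
#' @param K Number of studies (integer, at least 2).
#' @return The nonnegative noncentrality parameter.
#' @examples
#' noncentrality(0.5, K = 7) # 7
#' noncentrality(0.8, K = 7) # 28
#' @export
noncentrality <- function(iota2, K) {
  iota2 <- check_scalar_number(iota2, "iota2", min = 0, max = 1, strict_max = TRUE)
  K <- check_count(K, "K", min = 2L)
  K * iota2 / (1 - iota2)
}

#' Probability that the I-squared estimate is truncated to zero
#'
#' The truncated estimator is zero exactly when `Q < df`.  Under homogeneity
#' this is the central chi-square CDF at its own degrees of freedom -- always
#' above one half, however many studies there are.  Under the random-effects
#' model the event is `X < (1 - iota2) df` with `X` central chi-square; under
#' the fixed-effects model it is the noncentral chi-square CDF at `df`.
#'
#' @inheritParams noncentrality
#' @param model One of `"homogeneous"`, `"random"`, `"fixed"`.
#' @return A probability strictly between 0 and 1.
#' @examples
#' truncation_probability("homogeneous", K = 7)
#' truncation_probability("random", iota2 = 0.8, K = 7)
#' truncation_probability("fixed", iota2 = 0.8, K = 7)
#' @export
truncation_probability <- function(model, iota2 = 0, K) {
  sc <- check_scenario(model, iota2, K)
  switch(sc$model,
    homogeneous = pchisq(sc$df, sc$df),
    random = pchisq((1 - sc$iota2) * sc$df, sc$df),
    fixed = pchisq(sc$df, sc$df, ncp = noncentrality(sc$iota2, sc$K))
  )
}

#' Density of Cochran's Q under a heterogeneity model
#'
#' Evaluates the large-sample density of Q at `q` under the chosen model with
#' a common within-study standard error.
#'
#' @param q Evaluation point(s), nonnegative.
#' @inheritParams truncation_probability
#' @return Density values, same length as `q`.
#' @examples
#' q_density(6, "homogeneous", K = 7)
#' q_density(30, "random", iota2 = 0.8, K = 7)
#' @export
q_density <- function(q, model, iota2 = 0, K) {
  sc <- check_scenario(model, iota2, K)
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0)) {
    abort_invalid("`q` must be nonnegative and finite.")
  }
  switch(sc$model,
    homogeneous = dchisq(q, sc$df),
    random = (1 - sc$iota2) * dchisq((1 - sc$iota2) * q, sc$df),
    fixed = dchisq(q, sc$df, ncp = noncentrality(sc$iota2, sc$K))
  )
}

#' Cumulative distribution of Cochran's Q under a heterogeneity model
#'
#' @inheritParams q_density
#' @return `P(Q <= q)` under the stated model, same length as `q`.
#' @examples
#' q_cdf(6, "homogeneous", K = 7) # equals truncation_probability there
#' @export
q_cdf <- function(q, model, iota2 = 0, K) {
  sc <- check_scenario(model, iota2, K)
  if (!is.numeric(q) || any(is.na(q)) || any(q < 0)) {
    abort_invalid("`q` must be nonnegative.")
  }
  switch(sc$model,
    homogeneous = pchisq(q, sc$df),
    random = pchisq((1 - sc$iota2) * q, sc$df),
    fixed = pchisq(q, sc$df, ncp = noncentrality(sc$iota2, sc$K))
  )
}

# Quantile of Q under a model; used to cap quadrature ranges.
q_quantile <- function(p, model, iota2 = 0, K) {
  sc <- check_scenario(model, iota2, K)
  switch(sc$model,
    homogeneous = qchisq(p, sc$df),
    random = qchisq(p, sc$df) / (1 - sc$iota2),
    fixed = qchisq(p, sc$df, ncp = noncentrality(sc$iota2, sc$K))
  )
}
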