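# Exact expectation and bias of the heterogeneity-fraction estimators.
#
# Notation used throughout: df = K - 1, s = df/2, z = df (1 - iota2) / 2,
# lambda = K iota2 / (1 - iota2).  The truncated-estimator expectation under a
# central (possibly scaled) chi-square law has the closed form
#   E(I2) = ((s - 1 - z) Gamma(s - 1, z) + z^{s-1} e^{-z}) / Gamma(s),
# which reduces at iota2 = 0 (z = s) to the homogeneous expression
#   (df/(df-2)) ((df/2e)^{df/2} - Gamma(df/2, df/2)) / Gamma(df/2 + 1).
# It is evaluated through regularized incomplete-gamma ratios so it stays
# finite at large df (several hundred), where Gamma(s) itself overflows.

# -- closed forms -------------------------------------------------------------

# E(naive) under homogeneous/random models: 1 - df (1 - iota2)/(df - 2).
expected_naive_central <- function(iota2, df) {
  1 - df * (1 - iota2) / (df - 2)
}

# E(naive) under fixed effects with even df: the incomplete-gamma expression
#   1 + df 2^{s-2} e^{-l/2} (-1)^{-s} l^{1-s} (Gamma(s-1) - Gamma(s-1, -l/2))
# whose complex intermediates combine, for integer s, to the real value
#   1 + df 2^{s-2} (-1)^s l^{1-s} (s-2)! T_{s-1}(-l/2)
# with T_n the exponential Taylor tail (see special.R).
expected_naive_fixed_even <- function(iota2, K) {
  df <- K - 1L
  s <- df / 2
  if (iota2 == 0) {
    return(expected_naive_central(0, df))
  }
  lam <- K * iota2 / (1 - iota2)
  n <- s - 1L
  val <- 1 + df * 2^(s - 2) * (-1)^s * lam^(1 - s) *
    factorial(n - 1) * .taylor_tail(n, -lam / 2)
  if (!is.finite(val)) {
    abort_numeric(sprintf(
      "Even-df closed form lost precision at iota2 = %g, K = %d.", iota2, K
    ))
  }
  val
}

# E(I2) when Q is central chi-square scaled by 1/(1 - iota2); covers the
# homogeneous (iota2 = 0) and random-effects models.
expected_i2_central <- function(iota2, df) {
  s <- df / 2
  z <- df * (1 - iota2) / 2
  (s - 1 - z) * pgamma(z, s - 1, lower.tail = FALSE) / (s - 1) +
    exp((s - 1) * log(z) - z - lgamma(s))
}

expected_i2_closed <- function(model, iota2, df) {
  switch(model,
    homogeneous = expected_i2_central(0, df),
    random = expected_i2_central(iota2, df),
    abort_invalid("No closed form for the truncated estimator under fixed effects.")
  )
}

# -- quadrature ---------------------------------------------------------------

quad <- function(f, lower, upper, tol) {
  res <- tryCatch(
    integrate(f, lower, upper, abs.tol = tol, rel.tol = tol,
              subdivisions = 500L, stop.on.error = TRUE),
    error = function(e) {
      abort_numeric(sprintf("Quadrature failed on [%g, %g]: %s",
                            lower, upper, conditionMessage(e)))
    }
  )
  list(value = res$value, abs_error = res$abs.error)
}

# E(estimator) by adaptive quadrature of (1 - df/q) against the density of Q.
# The upper limit is the 1 - 1e-12 quantile of Q; the neglected tail of the
# bounded integrand (1 - df/q) < 1 contributes at most 1e-12.
expectation_by_quadrature <- function(model, iota2, K, estimator, tol = 1e-9) {
  df <- K - 1L
  upper <- q_quantile(1 - 1e-12, model, iota2, K)
  f <- function(q) (1 - df / q) * q_density(q, model, iota2, K)
  if (estimator == "truncated") {
    r <- quad(f, df, upper, tol)
  } else {
    # the integrand has an integrable singularity at q -> 0 for df > 2;
    # integrate the two sides of q = df separately
    r1 <- quad(f, 0, df, tol)
    r2 <- quad(f, df, upper, tol)
    r <- list(value = r1$value + r2$value, abs_error = r1$abs_error + r2$abs_error)
  }
  r
}

#' Brute-force expectation of a heterogeneity estimator
#'
#' Computes the expectation of the naive or truncated estimator by direct
#' adaptive quadrature of \eqn{(1 - df/q)} against the sampling density of Q
#' (see [q_density()]), making no use of any closed-form expression.  This is
#' the package's independent cross-check of every closed form.
#'
#' @inheritParams truncation_probability
#' @param estimator `"truncated"` (the I-squared statistic) or `"naive"`.
#' @param tol Absolute quadrature tolerance.
#' @return The expectation, a single number.
#' @examples
#' oracle_expectation("homogeneous", K = 7)                  # ~0.124
#' oracle_expectation("random", 0.8, K = 7, "naive")         # 0.7 exactly
#' @export
oracle_expectation <- function(model, iota2 = 0, K,
                               estimator = c("truncated", "naive"),
                               tol = 1e-9) {
  sc <- check_scenario(model, iota2, K)
  estimator <- rlang::arg_match(estimator)
  if (sc$df <= 2) {
    abort_undefined(sprintf(
      "The expectation is undefined for df = %d; at least 4 studies are needed.",
      sc$df
    ))
  }
  expectation_by_quadrature(sc$model, sc$iota2, sc$K, estimator, tol)$value
}

# -- user-facing dispatch -----------------------------------------------------

#' Exact expectation and bias of the I-squared estimators
#'
#' Evaluates the expectation of the naive estimator \eqn{1 - df/Q} or the
#' truncated estimator \eqn{\max(0, 1 - df/Q)} of the heterogeneity fraction,
#' together with its bias (expectation minus the true `iota2`) and the
#' probability that the truncated estimate is exactly zero.
#'
#' Closed forms are used wherever they exist: always for the homogeneous and
#' random-effects models, and for the naive estimator under fixed effects
#' when `df = K - 1` is even.  The truncated estimator under fixed effects
#' (and the odd-df naive case) is evaluated by adaptive quadrature against
#' the noncentral chi-square density.  The expectation exists only for
#' `df > 2`, i.e. at least 4 studies.
#'
#' @inheritParams truncation_probability
#' @param estimator `"truncated"` (the I-squared statistic) or `"naive"`.
#' @param method `"auto"` (closed form where available, else quadrature),
#'   `"closed_form"`, or `"numeric"`.
#' @param tol Absolute quadrature tolerance for numeric evaluation.
#' @return A one-row tibble with columns `estimator`, `model`, `iota2`, `K`,
#'   `df`, `expectation`, `bias`, `truncation_probability` (`NA` for the
#'   naive estimator), `method`, `abs_tolerance` (0 for closed forms).
#' @examples
#' i2_expectation("homogeneous", K = 7)           # expectation = bias ~ 0.12
#' i2_expectation("random", 0.8, K = 7)
#' i2_expectation("fixed", 0.8, K = 7)            # numeric integration
#' @export
i2_expectation <- function(model, iota2 = 0, K,
                           estimator = c("truncated", "naive"),
                           method = c("auto", "closed_form", "numeric"),
                           tol = 1e-9) {
  sc <- check_scenario(model, iota2, K)
  estimator <- rlang::arg_match(estimator)
  method <- rlang::arg_match(method)
  tol <- check_scalar_number(tol, "tol", min = 0, strict_min = TRUE)
  if (sc$df <= 2) {
    abort_undefined(sprintf(
      "E(%s estimator) is undefined for df = %d (needs df > 2, i.e. K >= 4).",
      estimator, sc$df
    ))
  }

  closed_available <-
    (estimator == "truncated" && (sc$model != "fixed" || sc$iota2 == 0)) ||
    (estimator == "naive" && (sc$model != "fixed" || sc$iota2 == 0 || sc$df %% 2 == 0))
  if (method == "closed_form" && !closed_available) {
    abort_invalid(
      "No closed form exists for this case; use method = \"auto\" or \"numeric\"."
    )
  }
  use_closed <- closed_available && method != "numeric"

  if (use_closed) {
    expectation <- if (estimator == "truncated") {
      if (sc$model == "fixed") {
        expected_i2_central(0, sc$df) # iota2 = 0 reduces to homogeneity
      } else {
        expected_i2_closed(sc$model, sc$iota2, sc$df)
      }
    } else {
      if (sc$model == "fixed") {
        expected_naive_fixed_even(sc$iota2, sc$K)
      } else {
        expected_naive_central(sc$iota2, sc$df)
      }
    }
    abs_tolerance <- 0
    method_used <- "closed_form"
  } else {
    r <- expectation_by_quadrature(sc$model, sc$iota2, sc$K, estimator, tol)
    expectation <- r$value
    abs_tolerance <- r$abs_error
    method_used <- "numeric_integration"
  }

  tibble(
    estimator = estimator,
    model = sc$model,
    iota2 = sc$iota2,
    K = sc$K,
    df = sc$df,
    expectation = expectation,
    bias = expectation - sc$iota2,
    truncation_probability = if (estimator == "truncated") {
      truncation_probability(sc$model, sc$iota2, sc$K)
    } else {
      NA_real_
    },
    method = method_used,
    abs_tolerance = abs_tolerance
  )
}

#' Bias curves over a grid of study counts and heterogeneity fractions
#'
#' Tabulates [i2_expectation()] over a grid, one row per `(iota2, K)` cell,
#' in the layout used by the package's bias-curve plots: expectation and bias
#' of the truncated (or naive) estimator as a function of the number of
#' studies.
#'
#' @inheritParams i2_expectation
#' @param iota2 Vector of heterogeneity fractions (forced to 0 for the
#'   homogeneous model).
#' @param K Vector of study counts (all at least 4).
#' @return A tibble with the columns of [i2_expectation()].
#' @examples
#' bias_curve("homogeneous", K = c(7, 10, 50))
#' bias_curve("random", iota2 = c(0.2, 0.8), K = c(5, 10, 20))
#' @export
bias_curve <- function(model, iota2 = seq(0.1, 0.9, by = 0.1), K = 4:100,
                       estimator = c("truncated", "naive"), tol = 1e-9) {
  model <- match_model(model)
  estimator <- rlang::arg_match(estimator)
  if (model == "homogeneous") iota2 <- 0
  grid <- tidyr::expand_grid(iota2 = unique(iota2), K = unique(as.integer(K)))
  purrr::pmap_dfr(grid, function(iota2, K) {
    i2_expectation(model, iota2, K, estimator = estimator, tol = tol)
  })
}
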