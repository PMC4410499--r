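# Monte Carlo simulator of synthetic meta-analyses.
#
# Emulates the equal-sigma, large-sample regime the analytic results assume:
# every study shares the true standard error sigma, and the reported standard
# errors equal that true sigma (no finite-sample noise in sigma-hat).  The
# implied between-study variance is tau2 = sigma^2 iota2 / (1 - iota2).

#' Draw true study effects under a heterogeneity model
#'
#' Generates the vector of true effects \eqn{\beta_k} for one synthetic
#' meta-analysis.  Homogeneous: all effects equal `mu`.  Random effects:
#' independent normal draws with mean `mu` and variance
#' \eqn{\tau^2 = \sigma^2 \iota^2/(1-\iota^2)} (uses the current RNG state).
#' Fixed effects: a deterministic, equally spaced, centered pattern rescaled
#' so the population variance (divide-by-K) of the effects equals
#' \eqn{\tau^2} exactly, which makes the noncentrality
#' \eqn{\lambda = K\iota^2/(1-\iota^2)} exact by construction.
#'
#' @inheritParams truncation_probability
#' @param sigma Common true within-study standard error (positive).
#' @param mu Grand mean effect.
#' @return A numeric vector of length `K`.
#' @examples
#' draw_true_effects("fixed", 0.8, K = 7) # sum((b - mean(b))^2) == 28
#' @export
draw_true_effects <- function(model, iota2 = 0, K, sigma = 1, mu = 0) {
  sc <- check_scenario(model, iota2, K)
  sigma <- check_scalar_number(sigma, "sigma", min = 0, strict_min = TRUE)
  mu <- check_scalar_number(mu, "mu")
  tau2 <- sigma^2 * sc$iota2 / (1 - sc$iota2)
  switch(sc$model,
    homogeneous = rep(mu, sc$K),
    random = rnorm(sc$K, mean = mu, sd = sqrt(tau2)),
    fixed = {
      if (tau2 == 0) {
        rep(mu, sc$K)
      } else {
        pattern <- seq_len(sc$K) - (sc$K + 1) / 2 # equally spaced, centered
        pop_var <- mean(pattern^2)
        mu + pattern * sqrt(tau2 / pop_var)
      }
    }
  )
}

#' Simulate one study set around given true effects
#'
#' Adds independent normal sampling noise with standard deviation `sigma` to
#' the true effects and reports `sigma` itself as each study's standard error
#' (the known-sigma asymptotic regime).  Uses the current RNG state.
#'
#' @param true_effects Numeric vector of true effects \eqn{\beta_k}.
#' @param sigma Common true within-study standard error (positive).
#' @return A study-set tibble with columns `study`, `effect`, `se`.
#' @examples
#' set.seed(1)
#' simulate_study_set(draw_true_effects("random", 0.5, K = 5), sigma = 1)
#' @export
simulate_study_set <- function(true_effects, sigma = 1) {
  if (!is.numeric(true_effects) || length(true_effects) < 2L ||
      any(!is.finite(true_effects))) {
    abort_invalid("`true_effects` must be a finite numeric vector of length >= 2.")
  }
  sigma <- check_scalar_number(sigma, "sigma", min = 0, strict_min = TRUE)
  K <- length(true_effects)
  as_study_set(tibble(
    study = paste0("study_", seq_len(K)),
    effect = true_effects + rnorm(K, sd = sigma),
    se = rep(sigma, K)
  ))
}

#' Monte Carlo expectation of the heterogeneity estimators
#'
#' Runs `n_reps` synthetic meta-analyses under the chosen model and estimates
#' the expectation of the truncated estimator `I2`, of the naive estimator,
#' and the truncation frequency `P(Q <= df)`, with Monte Carlo standard
#' errors.  Under the random-effects model fresh true effects are drawn every
#' replicate; under the fixed-effects model one deterministic effect pattern
#' (see [draw_true_effects()]) is held fixed across replicates, so the
#' noncentrality parameter is identical in every replicate.  Results are
#' reproducible: the same `seed` gives bit-identical output.
#'
#' @inheritParams draw_true_effects
#' @param n_reps Number of replicates (positive integer).
#' @param seed Integer seed for the simulation's private RNG.
#' @return A one-row tibble of class `i2_sim` with columns `model`, `iota2`,
#'   `K`, `sigma`, `mu`, `n_reps`, `seed`, `mean_I2`, `mc_se_I2`,
#'   `mean_naive`, `mc_se_naive`, `truncation_fraction`.
#' @examples
#' mc_expectation("homogeneous", K = 7, n_reps = 2000, seed = 1)
#' @export
mc_expectation <- function(model, iota2 = 0, K, sigma = 1, mu = 0,
                           n_reps = 10000, seed = 1) {
  sc <- check_scenario(model, iota2, K)
  sigma <- check_scalar_number(sigma, "sigma", min = 0, strict_min = TRUE)
  mu <- check_scalar_number(mu, "mu")
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)

  K <- sc$K
  df <- sc$df
  tau2 <- sigma^2 * sc$iota2 / (1 - sc$iota2)

  qs <- withr::with_seed(seed, {
    # K x n_reps matrix of estimated effects
    beta_hat <- switch(sc$model,
      homogeneous = mu + matrix(rnorm(K * n_reps, sd = sigma), K, n_reps),
      random = matrix(rnorm(K * n_reps, mean = mu, sd = sqrt(tau2 + sigma^2)),
                      K, n_reps),
      fixed = draw_true_effects("fixed", sc$iota2, K, sigma, mu) +
        matrix(rnorm(K * n_reps, sd = sigma), K, n_reps)
    )
    # equal sigma: the precision-weighted mean is the arithmetic column mean
    (colSums(beta_hat^2) - K * colMeans(beta_hat)^2) / sigma^2
  })

  naive <- 1 - df / qs
  i2 <- pmax(0, naive)
  structure(
    tibble(
      model = sc$model, iota2 = sc$iota2, K = K, sigma = sigma, mu = mu,
      n_reps = n_reps, seed = seed,
      mean_I2 = mean(i2), mc_se_I2 = sd(i2) / sqrt(n_reps),
      mean_naive = mean(naive), mc_se_naive = sd(naive) / sqrt(n_reps),
      truncation_fraction = mean(qs <= df)
    ),
    class = c("i2_sim", class(tibble())))
}
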