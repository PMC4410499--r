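# Shared fixtures and small independent simulators used across test files.

make_studies <- function(effects, ses) {
  tibble::tibble(
    study = paste0("s", seq_along(effects)),
    effect = effects,
    se = ses
  )
}

# A random valid study set (unequal standard errors), for property tests.
random_study_set <- function(K) {
  make_studies(rnorm(K, sd = 2), runif(K, 0.2, 3))
}

# Independent simulator of Cochran's Q under a model, written directly from
# the data-generating process (not via mc_expectation), for distributional
# checks.  Equal sigma = 1; returns n simulated Q values.
sim_Q <- function(model, iota2, K, n) {
  tau2 <- iota2 / (1 - iota2)
  beta_hat <- switch(model,
    homogeneous = matrix(rnorm(K * n), K, n),
    random = matrix(rnorm(K * n, sd = sqrt(tau2 + 1)), K, n),
    fixed = {
      pat <- seq_len(K) - (K + 1) / 2
      b <- pat * sqrt(tau2 / mean(pat^2))
      b + matrix(rnorm(K * n), K, n)
    }
  )
  colSums(beta_hat^2) - K * colMeans(beta_hat)^2
}

write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
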