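test_that("naive-estimator closed forms give their textbook values", {
  # homogeneity: E = bias = -2/(df - 2)
  expect_equal(i2_expectation("homogeneous", K = 7, estimator = "naive")$expectation, -0.5)
  expect_equal(i2_expectation("homogeneous", K = 5, estimator = "naive")$expectation, -1)
  expect_equal(i2_expectation("homogeneous", K = 103, estimator = "naive")$expectation, -0.02)
  # random effects: E = iota2 + (2 iota2 - 2)/(df - 2)
  expect_equal(i2_expectation("random", 0, K = 7, estimator = "naive")$expectation, -0.5)
  expect_equal(i2_expectation("random", 0.5, K = 7, estimator = "naive")$expectation, 0.25)
  expect_equal(i2_expectation("random", 0.8, K = 7, estimator = "naive")$expectation, 0.7)
  expect_equal(i2_expectation("random", 0.5, K = 7, estimator = "naive")$bias, -0.25)
})

test_that("expectations are undefined at df <= 2, with a distinct error class", {
  for (K in 2:3) {
    expect_error(i2_expectation("homogeneous", K = K),
                 class = "i2bias_undefined_expectation")
    expect_error(i2_expectation("random", 0.5, K = K, estimator = "naive"),
                 class = "i2bias_undefined_expectation")
    expect_error(oracle_expectation("fixed", 0.5, K = K),
                 class = "i2bias_undefined_expectation")
  }
  # ... and that class is not the plain invalid-input class
  err <- tryCatch(i2_expectation("homogeneous", K = 3), condition = identity)
  expect_false(inherits(err, "i2bias_invalid_input"))
})

test_that("every closed form agrees with brute-force quadrature to 1e-6", {
  grid <- tidyr::expand_grid(iota2 = seq(0, 0.9, by = 0.1), df = c(4, 6, 9, 20, 49))
  for (i in seq_len(nrow(grid))) {
    iota2 <- grid$iota2[i]; K <- grid$df[i] + 1L
    for (model in c("homogeneous", "random", "fixed")) {
      if (model == "homogeneous" && iota2 != 0) next
      for (estimator in c("naive", "truncated")) {
        closed_exists <- !(model == "fixed" && iota2 > 0 &&
                             (estimator == "truncated" || (K - 1) %% 2 == 1))
        if (!closed_exists) next
        closed <- i2_expectation(model, iota2, K, estimator = estimator,
                                 method = "closed_form")$expectation
        oracle <- oracle_expectation(model, iota2, K, estimator)
        expect_equal(closed, oracle, tolerance = 1e-6,
                     label = sprintf("%s/%s iota2=%g df=%d", model, estimator,
                                     iota2, K - 1))
      }
    }
  }
})

test_that("heterogeneous expectations reduce to the homogeneous form at iota2 = 0", {
  for (K in c(5, 7, 10, 50)) {
    e0 <- i2_expectation("homogeneous", K = K)$expectation
    expect_equal(i2_expectation("random", 0, K = K)$expectation, e0, tolerance = 1e-6)
    expect_equal(i2_expectation("fixed", 0, K = K)$expectation, e0, tolerance = 1e-6)
    # continuity just above zero
    expect_equal(i2_expectation("random", 1e-8, K = K)$expectation, e0,
                 tolerance = 1e-6)
    expect_equal(i2_expectation("fixed", 1e-8, K = K)$expectation, e0,
                 tolerance = 1e-5)
  }
})

test_that("expectation-result rows satisfy their structural invariants", {
  cases <- tidyr::expand_grid(model = c("random", "fixed"),
                              iota2 = c(0, 0.2, 0.5, 0.8), K = c(5, 8, 21))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      tr <- i2_expectation(model, iota2, K)
      nv <- i2_expectation(model, iota2, K, estimator = "naive")
      expect_identical(tr$bias, tr$expectation - iota2)
      expect_gte(tr$expectation, 0)
      expect_lt(tr$expectation, 1)
      expect_lte(nv$expectation, tr$expectation + 1e-12)
      expect_gt(tr$truncation_probability, 0)
      expect_lt(tr$truncation_probability, 1)
      expect_true(is.na(nv$truncation_probability))
      expect_identical(tr$abs_tolerance == 0, tr$method == "closed_form")
    })
  }
})

test_that("homogeneous truncation bias is positive and shrinks with more studies", {
  e <- vapply(3:200, function(df) {
    i2_expectation("homogeneous", K = df + 1)$expectation
  }, numeric(1))
  expect_true(all(e > 0))
  expect_true(all(diff(e) < 0)) # strictly decreasing in df
})

test_that("the bias switches sign above iota2 = .2 and fades for many studies", {
  for (model in c("random", "fixed")) {
    for (K in c(4, 7, 12, 20)) {
      expect_gt(i2_expectation(model, 0.1, K)$bias, 0,
                label = sprintf("%s K=%d iota2=.1", model, K))
      expect_lt(i2_expectation(model, 0.3, K)$bias, 0,
                label = sprintf("%s K=%d iota2=.3", model, K))
    }
  }
  for (K in c(10, 20, 50)) {
    expect_lt(abs(i2_expectation("random", 0.2, K)$bias), 0.02)
  }
  # consistency: with many studies the truncated estimator is nearly unbiased
  for (iota2 in c(0.3, 0.5, 0.8)) {
    for (df in c(500, 1000)) {
      expect_lt(abs(i2_expectation("random", iota2, df + 1)$bias), 0.01)
    }
  }
})

test_that("at strong heterogeneity the fixed-effects model is less biased", {
  expect_gt(i2_expectation("fixed", 0.8, K = 7)$expectation,
            i2_expectation("random", 0.8, K = 7)$expectation)
})

test_that("method dispatch: closed forms where they exist, quadrature elsewhere", {
  expect_identical(i2_expectation("random", 0.5, K = 7)$method, "closed_form")
  expect_identical(i2_expectation("fixed", 0.5, K = 7)$method, "numeric_integration")
  expect_identical(
    i2_expectation("fixed", 0.5, K = 7, estimator = "naive")$method, "closed_form"
  ) # df = 6 even
  expect_identical(
    i2_expectation("fixed", 0.5, K = 8, estimator = "naive")$method,
    "numeric_integration"
  ) # df = 7 odd
  expect_error(i2_expectation("fixed", 0.5, K = 8, estimator = "naive",
                              method = "closed_form"),
               class = "i2bias_invalid_input")
  # forcing quadrature must agree with the closed form
  expect_equal(i2_expectation("random", 0.7, K = 11, method = "numeric")$expectation,
               i2_expectation("random", 0.7, K = 11)$expectation, tolerance = 1e-7)
})

test_that("bias_curve tabulates the grid deterministically", {
  c1 <- bias_curve("random", iota2 = c(0.2, 0.8), K = c(5, 10, 20))
  expect_equal(nrow(c1), 6L)
  expect_named(c1, c("estimator", "model", "iota2", "K", "df", "expectation",
                     "bias", "truncation_probability", "method", "abs_tolerance"))
  expect_identical(c1, bias_curve("random", iota2 = c(0.2, 0.8), K = c(5, 10, 20)))
  # homogeneous curves ignore requested iota2 values
  ch <- bias_curve("homogeneous", iota2 = c(0.3, 0.6), K = c(7, 10))
  expect_equal(unique(ch$iota2), 0)
  expect_equal(nrow(ch), 2L)
})
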