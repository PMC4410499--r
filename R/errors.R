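# Condition helpers.  All package errors inherit from "i2bias_error" with a
# specific subclass so callers (and the CLI) can branch on the failure mode:
#   - i2bias_invalid_input:          malformed data or parameters
#   - i2bias_undefined_expectation:  expectation requested where it does not
#                                    exist (df <= 2)
#   - i2bias_numeric_error:          quadrature / special-function failure

abort_invalid <- function(message, ...) {
  abort(message, class = c("i2bias_invalid_input", "i2bias_error"), ...)
}

abort_undefined <- function(message, ...) {
  abort(message, class = c("i2bias_undefined_expectation", "i2bias_error"), ...)
}

abort_numeric <- function(message, ...) {
  abort(message, class = c("i2bias_numeric_error", "i2bias_error"), ...)
}

# Scalar-argument checks used across modules ---------------------------------

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    abort_invalid(sprintf(
      "`%s` must be in %s%s, %s%s; got %g.", name,
      if (strict_min) "(" else "[", format(min),
      format(max), if (strict_max) ")" else "]", x
    ))
  }
  as.numeric(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    abort_invalid(sprintf("`%s` must be a single whole number.", name))
  }
  if (x < min) {
    abort_invalid(sprintf("`%s` must be at least %d; got %g.", name, min, x))
  }
  as.integer(x)
}

# Model tags ------------------------------------------------------------------

#' @keywords internal
match_model <- function(model) {
  if (!is.character(model) || length(model) != 1L || is.na(model)) {
    abort_invalid("`model` must be one of \"homogeneous\", \"random\", \"fixed\".")
  }
  aliases <- c(
    homogeneous = "homogeneous", homogeneity = "homogeneous",
    random = "random", random_effects = "random", `random-effects` = "random",
    fixed = "fixed", fixed_effects = "fixed", `fixed-effects` = "fixed"
  )
  out <- unname(aliases[tolower(model)])
  if (is.na(out)) {
    abort_invalid(sprintf(
      "Unknown model \"%s\"; use \"homogeneous\", \"random\", or \"fixed\".", model
    ))
  }
  out
}

# Common (model, iota2, K) validation; returns a normalized list.
check_scenario <- function(model, iota2, K) {
  model <- match_model(model)
  iota2 <- check_scalar_number(iota2, "iota2", min = 0, max = 1, strict_max = TRUE)
  K <- check_count(K, "K", min = 2L)
  if (model == "homogeneous" && iota2 != 0) {
    abort_invalid("`iota2` must be 0 under the homogeneous model.")
  }
  list(model = model, iota2 = iota2, K = K, df = K - 1L)
}
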