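# Special functions backing the closed-form expectations.
#
# The closed forms need the upper incomplete gamma function Gamma(a, x) at
# real (possibly nonpositive) order a, and the generalized exponential
# integral E_nu(z) at real (possibly negative, non-integer) order nu.  Base R
# exposes only the regularized positive-order case through pgamma(); the
# extension to a <= 0 uses the downward-stable recurrence
#   Gamma(a, x) = (Gamma(a + 1, x) - x^a e^{-x}) / a,
# applied from the first positive order down.  E_nu(z) for z > 0 follows from
# the identity E_nu(z) = z^{nu - 1} Gamma(1 - nu, z).

#' Upper incomplete gamma function of real order
#'
#' Computes \eqn{\Gamma(a, x) = \int_x^\infty t^{a-1} e^{-t}\,dt} for real
#' order `a` (any sign) and `x > 0`.  For `a > 0` this is
#' `gamma(a) * pgamma(x, a, lower.tail = FALSE)`; for `a <= 0` the recurrence
#' \eqn{\Gamma(a, x) = (\Gamma(a+1, x) - x^a e^{-x})/a} is applied.
#'
#' @param a Real order (scalar or vector).
#' @param x Evaluation point, strictly positive (scalar or vector).
#' @return `Gamma(a, x)`, vectorized over the common length of `a` and `x`.
#' @examples
#' inc_gamma_upper(3, 3)            # integer order
#' inc_gamma_upper(-0.5, 1.2)       # negative real order
#' @export
inc_gamma_upper <- function(a, x) {
  if (!is.numeric(a) || !is.numeric(x) || any(!is.finite(a)) || any(!is.finite(x))) {
    abort_invalid("`a` and `x` must be finite numerics.")
  }
  if (any(x <= 0)) {
    abort_invalid("`x` must be strictly positive.")
  }
  n <- max(length(a), length(x))
  a <- rep_len(a, n)
  x <- rep_len(x, n)
  vapply(seq_len(n), function(i) .inc_gamma_upper1(a[i], x[i]), numeric(1))
}

.inc_gamma_upper1 <- function(a, x) {
  if (a > 0) {
    return(exp(lgamma(a) + pgamma(x, a, lower.tail = FALSE, log.p = TRUE)))
  }
  # anchor at the smallest reachable order in [0, 1): Gamma(0, x) = E_1(x) for
  # integer a, the fractional part of a otherwise; then step down with
  #   Gamma(b - 1, x) = (Gamma(b, x) - x^{b-1} e^{-x}) / (b - 1),
  # whose divisors never hit zero below the anchor.
  b <- a - floor(a)
  if (b == 0) {
    g <- .expint_e1(x)
  } else {
    g <- exp(lgamma(b) + pgamma(x, b, lower.tail = FALSE, log.p = TRUE))
  }
  while (b > a + 0.5) {
    b <- b - 1
    g <- (g - x^b * exp(-x)) / b
  }
  g
}

# Classical exponential integral E_1(x) = Gamma(0, x), x > 0: power series
# near the origin, modified-Lentz continued fraction elsewhere.
.expint_e1 <- function(x) {
  if (x <= 1.5) {
    total <- -0.577215664901532861 - log(x)
    term <- 1
    for (k in 1:60) {
      term <- term * (-x) / k
      total <- total - term / k
      if (abs(term / k) < 1e-18 * abs(total)) break
    }
    total
  } else {
    b <- x + 1
    c <- 1 / .Machine$double.xmin
    d <- 1 / b
    h <- d
    for (i in 1:200) {
      an <- -i * i
      b <- b + 2
      d <- 1 / (an * d + b)
      c <- b + an / c
      del <- c * d
      h <- h * del
      if (abs(del - 1) < 1e-16) break
    }
    h * exp(-x)
  }
}

#' Generalized exponential integral of real order
#'
#' Computes \eqn{E_\nu(z) = \int_1^\infty e^{-zt} t^{-\nu}\,dt} for real order
#' `nu` (any sign, not necessarily integer) and `z > 0`, via the identity
#' \eqn{E_\nu(z) = z^{\nu-1}\,\Gamma(1-\nu, z)}.
#'
#' @param nu Real order (scalar or vector).
#' @param z Argument, strictly positive (scalar or vector).
#' @return `E_nu(z)`, vectorized over the common length of `nu` and `z`.
#' @examples
#' expint_en(1, 1)      # the classical E_1
#' expint_en(-3, 0.6)   # negative order, as used by the bias closed forms
#' @export
expint_en <- function(nu, z) {
  if (!is.numeric(nu) || !is.numeric(z) || any(!is.finite(nu)) || any(!is.finite(z))) {
    abort_invalid("`nu` and `z` must be finite numerics.")
  }
  if (any(z <= 0)) {
    abort_invalid("`z` must be strictly positive.")
  }
  z^(nu - 1) * inc_gamma_upper(1 - nu, z)
}

# Exponential Taylor tail T_n(x) = sum_{j >= n} x^j / j! = e^x - S_{n-1}(x),
# where S_m is the order-m Taylor partial sum of e^x.  Needed at x = -lambda/2
# by the even-df fixed-effects closed form, whose printed complex intermediates
# (-1)^{-df/2} and Gamma(df/2 - 1, -lambda/2) combine to
#   e^{-lambda/2} gamma_lower(n, -lambda/2) = (n-1)! T_n(-lambda/2).
# Two stable regimes for x < 0:
#   |x| <= n : the tail terms alternate with immediately decreasing magnitude,
#              so direct summation is accurate (no O(e^{|x|}) head to cancel);
#   |x| >  n : e^x is negligible against the growing partial sum, so the
#              difference form e^x - S_{n-1}(x) is exact to working precision.
.taylor_tail <- function(n, x) {
  if (abs(x) <= n) {
    term <- x^n / factorial(n)
    total <- term
    j <- n
    while (abs(term) > 1e-18 * max(1, abs(total)) && j < n + 2000) {
      j <- j + 1
      term <- term * x / j
      total <- total + term
    }
    total
  } else {
    j <- seq_len(n) - 1
    exp(x) - sum(x^j / factorial(j))
  }
}
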