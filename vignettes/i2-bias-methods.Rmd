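---
title: "Expectation and bias of the I² heterogeneity statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expectation and bias of the I² heterogeneity statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(i2bias)
```

## The estimand and the estimators

A meta-analysis summarizes $K$ studies, each reporting an effect estimate
$\hat\beta_k$ with standard error $\hat\sigma_k$.  The estimates vary across
studies partly because of sampling error and partly because the true effects
$\beta_k$ themselves differ — *heterogeneity*.  Writing $\tau^2 = V(\beta_k)$
for the between-study variance and $\sigma^2 = E(\sigma_k^2)$ for the average
within-study variance, the fraction of the variance in $\hat\beta_k$ that is
due to heterogeneity is

$$\iota^2 \;=\; \frac{\tau^2}{\tau^2 + \sigma^2} \in [0, 1).$$

The standard point estimator starts from Cochran's
$Q = \sum_k (\hat\beta_k - \hat{\bar\beta})^2/\hat\sigma_k^2$, with
$\hat{\bar\beta}$ the precision-weighted mean, and forms the naive moment
estimator and its truncation:

$$\hat\iota^2 = 1 - \frac{df}{Q}, \qquad
  I^2 = \max(0,\ \hat\iota^2), \qquad df = K - 1 .$$

The naive estimator is negative whenever $Q < df$; the truncation that makes
$I^2$ presentable is also what makes it biased upward near homogeneity.
`estimate_heterogeneity()` computes all of these from a study-level data
frame; this vignette describes the analytic machinery behind
`i2_expectation()`, which evaluates the *exact* expectation and bias of both
estimators, and the Monte Carlo simulator that cross-checks it.

## Sampling models for Q

Three data-generating models are supported, all in the equal-$\sigma$,
large-within-study-sample regime where $\hat\beta_k \mid \beta_k \sim
N(\beta_k, \sigma^2)$ with $\sigma$ known:

* **homogeneous** — all $\beta_k$ equal; $Q \sim \chi^2_{df}$.
* **random effects** — $\beta_k \sim N(\mu, \tau^2)$ independently, so
  $\hat\beta_k$ are i.i.d. $N(\mu, \tau^2 + \sigma^2)$ and
  $X = (1 - \iota^2)\,Q \sim \chi^2_{df}$.
* **fixed effects** — the $\beta_k$ are fixed constants;
  $Q \sim \chi^2_{df}(\lambda)$, noncentral with
  $\lambda = \sum_k (\beta_k - \bar\beta)^2 / \sigma^2
  = K\,\iota^2 / (1 - \iota^2)$ when the population (divide-by-$K$) variance
  of the fixed effects is identified with $\tau^2$.

All three coincide at $\iota^2 = 0$.  The equal-$\sigma$ simplification is
what gives $Q$ these clean chi-square forms; with unequal $\sigma_k$ the
random-effects $Q$ is a general weighted sum of chi-squares, which the
analytic layer deliberately does not model (see *Limitations*).
`q_density()`, `q_cdf()` and `truncation_probability()` expose these laws;
the latter gives $P(I^2 = 0) = P(Q < df)$, which under homogeneity is
$P(\chi^2_{df} < df) > 1/2$ for every $df$ — a zero estimate is always the
more likely outcome in a homogeneous meta-analysis.

## Closed-form expectations

With $s = df/2$ and $z = df\,(1 - \iota^2)/2$, the expectations used by the
package are:

* **Naive, homogeneous or random effects.**  $1/Q$ is a (scaled) inverse
  chi-square, so
  $E(\hat\iota^2) = 1 - df\,(1-\iota^2)/(df - 2)$, and the bias
  $(2\iota^2 - 2)/(df - 2)$ is always negative.  It exists only for
  $df > 2$: for $df \le 2$ the package raises a distinct
  *undefined-expectation* error rather than returning a number.
* **Truncated, homogeneous or random effects.**  Conditioning on the
  truncation event,
  $E(I^2) = P(Q > df)\,E(1 - df/Q \mid Q > df)$, and integrating
  $(1 - df/q)$ against the scaled chi-square density gives

  $$E(I^2) \;=\; \frac{(s - 1 - z)\,\Gamma(s - 1, z) + z^{\,s-1} e^{-z}}
                      {\Gamma(s)},$$

  where $\Gamma(\cdot,\cdot)$ is the upper incomplete gamma function.  At
  $\iota^2 = 0$ (i.e. $z = s$) this reduces to the homogeneous form
  $\frac{df}{df-2}\,\bigl[(df/2e)^{df/2} - \Gamma(df/2, df/2)\bigr] /
  \Gamma(df/2 + 1)$.  The same expression can be written with real-order
  generalized exponential integrals through
  $E_\nu(z) = z^{\nu-1}\Gamma(1-\nu, z)$; `expint_en()` and
  `inc_gamma_upper()` implement that machinery for any real order, since
  standard libraries stop at positive integer orders.
* **Naive, fixed effects, even $df$.**  The expectation
  $1 - df\,E(1/Q)$ for noncentral $Q$ has the closed form
  $1 + df\,2^{s-2} e^{-\lambda/2} (-1)^{-s} \lambda^{1-s}
  \bigl(\Gamma(s{-}1) - \Gamma(s{-}1, -\lambda/2)\bigr)$, which is real only
  for even $df$.  Although written with complex intermediates, for integer
  $s$ it simplifies exactly to
  $1 + df\,2^{s-2}(-1)^s \lambda^{1-s} (s-2)!\;T_{s-1}(-\lambda/2)$ with
  $T_n(x) = \sum_{j \ge n} x^j/j!$ the exponential Taylor tail, and the
  package evaluates that real form directly.  $T_n$ is computed by direct
  tail summation when $|x| \le n$ (where the subtractive form
  $e^x - S_{n-1}$ would cancel catastrophically) and by the difference form
  otherwise; both regimes are accurate to near machine precision.
* **Everything else** — the truncated estimator under fixed effects with
  $\iota^2 > 0$, and the odd-$df$ fixed-effects naive case — has no workable
  closed form and is evaluated by adaptive quadrature of $(1 - df/q)$
  against the noncentral chi-square density.

Every closed form is verified two independent ways: against
`oracle_expectation()`, a brute-force quadrature that never touches the
closed-form code path, to within $10^{-6}$ over a grid of
$\iota^2 \in \{0, .1, \dots, .9\}$ and $df \in \{4, 6, 9, 20, 49\}$; and
against the Monte Carlo simulator within Monte Carlo error.

## What the bias looks like

```{r, eval = FALSE}
bias_curve("homogeneous", K = c(7, 10, 50))[, c("K", "expectation")]
#>       K expectation
#>       7      0.1245
#>      10      0.1124
#>      50      0.0636
```

Under homogeneity the bias *is* the expectation, always positive, large for
small meta-analyses (0.12 at $K = 7$) and decaying slowly (still 0.06 at
$K = 50$).  Under heterogeneity two opposing forces act: truncation pushes
the expectation up, while the negative bias of the naive estimator pulls it
down.  The net effect switches sign: positive bias at $\iota^2 = .1$,
essentially none at $\iota^2 = .2$, negative above.  At strong heterogeneity
the fixed-effects model is markedly less biased than the random-effects
model — at $\iota^2 = .8$, $K = 7$ the package computes $E(I^2) = 0.80$
under fixed effects and $0.71$ under random effects.
`plot_bias_curve(bias_curve("random"))` draws the full picture.

## The simulator: what it emulates, and what it does not

`mc_expectation()` generates synthetic meta-analyses exactly under the
analytic assumptions: a common, known within-study standard error `sigma`
(default 1 — only the ratio $\tau/\sigma$ matters, since $Q$, $\hat\iota^2$
and $I^2$ are invariant to common rescaling), grand mean `mu` (default 0;
all outputs are shift-invariant, which is asserted as a test), and
$\tau^2 = \sigma^2\iota^2/(1-\iota^2)$.  Random-effects replicates redraw
$\beta_k \sim N(\mu, \tau^2)$ every time; fixed-effects replicates hold one
deterministic, equally spaced, centered pattern of effects — rescaled once
so the population variance matches $\tau^2$ exactly, making $\lambda$ exact
by construction — and redraw only the sampling noise.  Normality of the
random effects is a modelling choice: only their variance is pinned down by
the estimand, but normality is what makes the scaled-chi-square law of $Q$
exact.

Each call seeds one private RNG (`withr::with_seed`), so identical
specifications give bit-identical results and the global RNG state is left
untouched.

Deliberately *not* emulated: estimated standard errors (the simulator
reports the true $\sigma$, matching the large-sample regime the analytic
results live in), unequal $\sigma_k$, non-normal random effects, and
patient-level data.  A passing Monte Carlo suite therefore certifies the
analytic formulas under their own assumptions; it says nothing about how
$I^2$ behaves when within-study variances are themselves noisy estimates
from small studies — a genuinely different (and harder) regime.

## Numerical choices

* Quadrature is `stats::integrate()` with absolute tolerance $10^{-9}$
  (tunable via `tol`).  Infinite upper limits are replaced by the
  $1 - 10^{-12}$ quantile of the relevant distribution: the integrand is
  bounded by 1, so the neglected tail is below $10^{-12}$, and a finite
  range keeps the adaptive transform from missing far-shifted noncentral
  peaks (relevant once $\lambda$ is in the hundreds).
* Naive-estimator integrals have an integrable singularity of
  $q^{df/2 - 2}$ order at the origin for $df > 2$; the range is split at
  $q = df$ so the singular piece is integrated on its own.
* $Q = 0$ (all effects identical) makes $1 - df/Q$ undefined; the naive
  estimator returns $-\infty$ with a warning and truncation maps it to 0,
  which is the value the estimator's definition intends.  A tie $Q = df$
  gives $I^2 = 0$ (a measure-zero event; either argument of the max attains
  it).
* $\Gamma(a, x)$ at nonpositive real order is anchored at
  $\Gamma(0, x) = E_1(x)$ (power series below $x = 1.5$, modified-Lentz
  continued fraction above) or at the fractional part of $a$, then stepped
  down by the recurrence $\Gamma(b-1,x) = (\Gamma(b,x) - x^{b-1}e^{-x})/(b-1)$.
* The central closed forms are evaluated through regularized
  incomplete-gamma *ratios* (`pgamma` on the log scale), so they remain
  finite at $df$ in the hundreds where $\Gamma(s)$ itself overflows; the
  large-$K$ consistency checks run at $df = 1000$ without special handling.
* Expectations at $df \le 2$ raise an `i2bias_undefined_expectation`
  condition, distinct from `i2bias_invalid_input`.  (At $df = 2$ the
  truncated-estimator *integral* still converges, but the estimator's
  expectation is conventionally treated as undefined together with the
  naive one, whose $E(1/Q)$ genuinely diverges; the package follows that
  convention rather than special-casing $df = 2$.)

## Validation problem sizes

The shipped test suite checks: all closed forms against the quadrature
oracle on the $10 \times 5$ grid above; distributional identities of $Q$ by
Kolmogorov–Smirnov tests at $10^4$ replicates per model; and the Monte Carlo
grid (three models, $\iota^2 \in \{0, .1, .5, .8\}$,
$K \in \{5, 7, 10, 50\}$) at $10^5$ replicates per cell against the analytic
expectations within three Monte Carlo standard errors, allowing the single
marginal exceedance that a 36-cell grid is expected to produce by chance.
These sizes were chosen so the whole suite certifies the formulas to well
under a percentage point while running in well under a minute.

## Limitations

* The analytic layer assumes a common within-study standard error.  Real
  meta-analyses have unequal $\hat\sigma_k$; `estimate_heterogeneity()`
  handles them exactly (the weighting is general), but the *bias* results
  apply to the equal-$\sigma$ idealization.
* All results are large-within-study-sample asymptotics with known
  $\sigma$; finite-sample noise in $\hat\sigma_k$ is out of scope.
* The package quantifies the bias of $I^2$; it neither proposes a
  bias-corrected estimator (any nonnegative estimator must be biased near
  $\iota^2 = 0$) nor computes confidence intervals for $\iota^2$ — interval
  methods exist and are the right complement to a point estimate in small
  meta-analyses, but they are a separate undertaking.
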