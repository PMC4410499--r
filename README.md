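# i2bias

Exact expectation and bias of the I² heterogeneity statistic in
meta-analysis, with estimators, analytic curves, and a Monte Carlo
verifier.

## The problem

A meta-analysis pools $K$ study estimates $\hat\beta_k$ with standard errors
$\hat\sigma_k$.  The fraction of the between-study variance that reflects
real heterogeneity rather than sampling error,

$$\iota^2 = \frac{\tau^2}{\tau^2 + \sigma^2},$$

is universally estimated by the I² statistic: with Cochran's
$Q = \sum_k (\hat\beta_k - \hat{\bar\beta})^2/\hat\sigma_k^2$ and
$df = K - 1$,

$$\hat\iota^2 = 1 - \frac{df}{Q}, \qquad I^2 = \max(0,\ \hat\iota^2).$$

Because $\hat\iota^2$ is negative whenever $Q < df$ — an event with
probability above one half under homogeneity — the truncation biases $I^2$
upward near $\iota^2 = 0$, while the naive estimator's own negative bias
dominates at large $\iota^2$.  Most published meta-analyses are small
(median around 7 studies), where both effects are far from negligible.
This package computes the statistics from data and, more importantly,
evaluates the **exact** expectation and bias of both estimators under three
data-generating models (homogeneous, random effects, fixed effects, all
with a common within-study standard error), by closed forms built on upper
incomplete gamma functions and real-order exponential integrals, by
adaptive quadrature against the (noncentral) chi-square law of $Q$, and by
seeded simulation.  It is aimed at meta-analysts and methodologists who
need to know how much of a reported I² is estimator artifact.

## Worked example

Estimate heterogeneity from a CSV (one row per study; a small synthetic
7-trial set ships with the package):

```r
library(i2bias)

csv <- system.file("extdata", "synthetic_trials.csv", package = "i2bias")
fit <- estimate_heterogeneity(read_studies(csv))
fit
#> Heterogeneity of 7 studies (df = 6)
#>   weighted mean effect: 0.3631
#>   Cochran's Q:          2.237
#>   naive iota^2:         -1.682
#>   I^2:                  0
#>   If the studies were homogeneous, E(I^2) would still be 0.12 at df = 6.
#>   Note: with few studies I^2 is imprecise and can be substantially biased;
#>   interpret the point estimate cautiously.
```

`Q` fell below its 6 degrees of freedom, so the naive estimator is negative
and I² is truncated to zero — the typical outcome in a small homogeneous
meta-analysis.  `glance(fit)` and `tidy(fit)` return the same numbers as
tibbles; `autoplot(fit)` shows per-study contributions to Q.

How biased is I² in a setting like this?  Ask for the exact expectation:

```r
i2_expectation("random", iota2 = 0.8, K = 7)
#> # A tibble: 1 x 10
#>   estimator model  iota2     K    df expectation    bias truncation_probability
#>   <chr>     <chr>  <dbl> <int> <int>       <dbl>   <dbl>                  <dbl>
#> 1 truncated random   0.8     7     6       0.713 -0.0865                 0.0231
```

With 7 studies and 80 % true heterogeneity under a random-effects model,
I² is expected to read 0.71 — an underestimate of about 9 percentage
points — and is truncated to zero in about 2 % of meta-analyses.  Under
homogeneity the same call gives an expectation (= bias) of **0.12** at
K = 7, 0.11 at K = 10, 0.06 at K = 50; under fixed effects at
$\iota^2 = .8$ the expectation is **0.80**, nearly unbiased.  A Monte Carlo
check of the random-effects value:

```r
mc_expectation("random", 0.8, K = 7, n_reps = 1e5, seed = 42)
#>   mean_I2 = 0.7139 (mc se 0.0006), mean_naive = 0.7011, truncation_fraction = 0.0227
```

`bias_curve()` tabulates expectation and bias over a (ι², K) grid and
`plot_bias_curve()` draws it; `oracle_expectation()` recomputes any
expectation by brute-force quadrature, independently of the closed forms.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/i2bias.R bias --model random --iota2 0.8 --k 7
Rscript inst/cli/i2bias.R estimate --input studies.csv --format json
Rscript inst/cli/i2bias.R curve --model fixed --output curves.csv
Rscript inst/cli/i2bias.R simulate --model random --iota2 0.8 --k 7 --reps 100000 --seed 42
```

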