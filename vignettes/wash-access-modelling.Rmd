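---
title: "Modelling drinking-water and sanitation access panels with washbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drinking-water and sanitation access panels with washbayes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(washbayes)
```

## The scientific problem

National access rates to drinking water and sanitation — the share of a
country's population with at least basic or with safely managed service, as
published in WHO/UNICEF JMP-style service-ladder tables — rose almost
everywhere between 2000 and 2020. A raw comparison of the two years,
however, confounds progress in water and sanitation provision with general
socioeconomic development: richer, more urban, more democratic countries
have systematically higher access. washbayes implements a pipeline that
separates the two, by asking whether the access rate a country achieves *at
a fixed level of socioeconomic, political and hydrological development*
went up or down across two reference years, and which national conditions
are associated with the *improvement* a country achieved over the period.

## The model

The access rate $C$ of a country-year is modelled with a logistic mean and
additive Gaussian error on the rate scale:

$$
P \;=\; \frac{\exp(\beta_0 + C_d X_d + \sum_i C_i X_i)}
             {1+\exp(\beta_0 + C_d X_d + \sum_i C_i X_i)},
\qquad
C \sim \mathrm{normal}(P,\ \sigma).
$$

The logistic mean keeps the expected rate inside $(0,1)$ and encodes
diminishing marginal gains near full coverage. The $X_i$ are normalized
covariates (log$_{10}$ GDP per capita, urban population rate, democracy
index, log$_{10}$ renewable internal freshwater resources per capita) and
$X_d$ is a 0/1 dummy that is 0 for the earlier and 1 for the later year.
Because the covariates are z-scored over the stacked rows of both years,
$C_d$ is a pure cross-year contrast: the shift, on the logit scale, of the
access rate achievable at identical covariate values. A significantly
negative $C_d$ means the later year *underperforms* the earlier year once
development is held fixed.

Two deliberate features of the likelihood deserve emphasis:

* The Gaussian error is **untruncated**. Observed rates of exactly 0 or 1
  are valid data, and nothing clips model draws or synthetic data to
  $[0,1]$. This keeps the likelihood simple and the parameter-recovery
  simulations exact-model tests.
* The error is on the **rate scale**, not the logit scale, so $\sigma$ is
  directly interpretable as a rate-unit residual standard deviation
  (typical posterior values on realistic panels are a few percentage
  points).

Priors are independent normal(0, 50) on the intercept and every
coefficient — effectively flat over any plausible logit-scale value — and
half-normal(50) on $\sigma$ (a normal(0, 50) truncated to the positive
half-line; the two readings of "all parameters have a normal prior"
coincide). An improper flat prior on $\sigma$ is available as a
configuration switch (`model_spec(sigma_prior = "flat")`); with the amount
of data in these panels the two are numerically indistinguishable.

### The improvement statistic

For the second question the package computes, per country, the
attributable proportion

$$
P_2 = \frac{C_\mathrm{later} - C_\mathrm{prev}}{C_\mathrm{later}},
$$

the share of the later year's coverage that was gained during the period
(0.5 means half of the infrastructure serving people at the later year was
added in the interval). $P_2$ is scale-invariant, at most 1, and undefined
when the later rate is 0. Values slightly below 0 arise from measurement
error; countries with $P_2 < -0.05$ (strictly) are excluded and reported by
name, while values in $[-0.05, 0)$ are retained and enter the Gaussian
likelihood untouched — the logistic mean cannot reach them, which the
untruncated error model tolerates by design. $P_2$ is then regressed, with
the same logistic-mean Gaussian-error model but no dummy, on z-scored
**period-mean** covariates: each factor is transformed first (log first for
the skewed monetary/hydrological series) and the transformed annual values
are averaged over the full period, a geometric-mean-like summary for the
skewed series. The alternative average-then-transform policy is exposed as
a switch (`mean_covariates(..., policy =)`) because the two genuinely
differ — for GDP values $\{100, 1000, 10000\}$ the transformed mean is 3.0
while the mean-then-log value is $\log_{10} 3700 \approx 3.57$.

## Preprocessing decisions

**Normalization.** Each covariate column is z-scored (mean 0, sd 1, $n-1$
denominator) over the *pooled* stacked rows of the two analysis years,
after its transform. Pooling keeps one scale for both dummy levels, which
is what makes $C_d$ interpretable; per-year normalization is available as
a switch (`build_dataset(normalize = "per_year")`) for sensitivity checks.
A useful corollary of transform-then-z-score is that the base of the
logarithm is irrelevant — a base change is an affine map absorbed exactly by
the z-score — which the test suite verifies to $10^{-12}$.

**Complete cases.** The analysis unit is the country-year: a country
observed in only one year still contributes that row. The stricter rule
(both years or nothing) is available via `complete_unit = "country"`.
Missing values are dropped and counted at read time, never imputed.

**Basic-or-higher aggregation.** JMP ladders publish both disjoint levels
(safely managed; basic) and the cumulative "at least basic" category.
The analysis category "basic or higher" therefore uses an existing
`at_least_basic` row verbatim when present and otherwise sums the two
disjoint levels; summing all three would double-count. A computed sum
exceeding 1 by more than $10^{-9}$ signals inconsistent ladder input and is
an error naming the offending key, never a silent clip. The all-sum policy
remains selectable (`policy = "sum_components"`).

**Democracy index.** The index series begins in 2006, so analyses anchored
at 2000 copy each country's 2006 score to 2000
(`carry_democracy_2006_to_2000()`); existing 2000 values are never
overwritten and the number of carried records is logged.

**Dialects.** File layout (delimiter, column names, percent vs proportion,
wide vs long) is always declared up front in a dialect object, never
sniffed. A dialect-level `range = "extended"` switch admits rates slightly
outside $[0,1]$; it exists because the untruncated Gaussian observation
model of the synthetic generator legitimately produces such rates, while
real JMP exports are validated strictly against the unit interval.

## Posterior computation

Sampling is by adaptive random-walk Metropolis over
$(\beta_0, C_i, C_d, \sigma)$ jointly, implemented in C++:

1. A Laplace approximation (posterior mode by L-BFGS-B, covariance from the
   inverse Hessian at the mode) preconditions the proposal and supplies
   jittered chain starting points. For a zero-row (prior-only) fit, where
   the half-normal mode of $\sigma$ sits on the boundary, the prior's own
   scale is used instead.
2. During warm-up the proposal covariance additionally tracks the running
   covariance of visited states scaled by $2.38^2/d$ (Haario-style), and a
   global log-scale follows a Robbins–Monro recursion toward an acceptance
   rate of 0.3. Both adaptations freeze at the end of warm-up, so retained
   draws come from a fixed Markov kernel.
3. Proposals with $\sigma \le 0$ are rejected through a $-\infty$
   log-posterior; no reparameterization is needed.

The default protocol is 10,000 iterations per chain of which 2,000 are
warm-up (8,000 retained), 4 chains. Convergence is declared when the
split-chain Gelman–Rubin statistic,
$\hat R = \sqrt{(W(n-1)/n + B/n)/W}$ with every chain split in half, is
below 1.10 for all parameters; non-convergence produces a warning and a
flagged result, not an error, so exploratory screening runs can complete.
Summaries are posterior means and central (equal-tailed) 95% credible
intervals from the pooled post-warm-up draws; a parameter is flagged
significant when that interval excludes 0. All summaries are reproducible
bit-for-bit from the seed, and the log posterior keeps every normalizing
constant so it can be checked term-by-term against independent density
summation (the suite requires agreement to $10^{-10}$).

## What the synthetic generator emulates — and what it does not

`generate_study()` draws country panels with the statistical structure the
analysis assumes: covariates sampled on the transformed scale from a
correlated Gaussian (defaults: log$_{10}$ GDP mean 3.7 sd 0.6; urban rate
mean 55 sd 20; democracy mean 5.5 sd 2; log$_{10}$ water mean 3.3 sd 0.7;
wealth–urbanization correlation 0.6, wealth–democracy 0.5,
urbanization–democracy 0.35; a two-decade drift of +0.2 log$_{10}$ units
of GDP and +5 urbanization points), access rates generated exactly from
the logistic-mean Gaussian-error model with true coefficients
$(\beta_0, C_\mathrm{GDP}, C_\mathrm{urban}, C_\mathrm{dem}, C_d) =
(2.0, 1.0, 0.3, 0.1, -0.5)$ and $\sigma = 0.05$ over 150 countries and two
years, plus ladder rows consistent with the aggregation policy and
optional per-factor missingness and the 2006-democracy gap. These defaults
are the package's reference study conditions and are deliberately not
tuned per test.

The generator does **not** attempt to mimic real country identities,
income distributions, JMP survey error structure, or spatial/temporal
autocorrelation. Passing recovery tests therefore demonstrates that the
estimation machinery is correct *under the model's own assumptions* — they
say nothing about whether the model is adequate for real JMP data, which
is a scientific judgement outside the package's scope. The bundled
`inst/extdata` example files are likewise synthetic illustrative values in
realistic ranges, not real JMP or World Bank records.

## Validation performed by the test suite

* The joint log posterior matches an independent term-by-term density
  summation to $10^{-10}$ on a fixed 5-row dataset.
* Across 20 seeded replicates of the reference access-rate scenario
  (150 countries × 2 years, 3 covariates + dummy, $\sigma = 0.05$, 2
  chains × 3,000 retained draws), each true coefficient falls inside its
  95% credible interval in at least 17 replicates and mean absolute bias
  of the posterior means stays below 0.05; the same holds for the
  improvement regression (140 countries, 4 covariates, no dummy).
* $\hat R$ and variance inflation factors match closed-form /
  normal-equations oracles to $10^{-6}$ and $10^{-8}$.
* A hand-built six-country improvement table is reproduced exactly,
  including the strict behaviour at the $-0.05$ boundary.
* With no data, posterior draws reproduce the prior scale (sd 50) within
  10%; with vanishing observation noise, coefficients are recovered within
  0.02.

These problem sizes (a few hundred rows, a few thousand retained draws per
chain) keep the default validation run to a few seconds while leaving
Monte Carlo error comfortably inside the asserted tolerances; the same
machinery scales unchanged to the full default protocol.

## Known limitations

* The Gaussian rate-scale error is heteroscedasticity-blind: countries
  near 0 or 1 coverage have bounded, skewed errors that the model treats
  as symmetric. The untruncated likelihood is an approximation chosen for
  interpretability and exact testability, not a claim about the data.
* No hierarchical country effects, spatial correlation, or model
  comparison (WAIC/LOO) — the pipeline fits none by design.
* Significance is per-parameter by 95% credible interval; no multiplicity
  adjustment is applied across the many (service, quality, area, era)
  configurations, and none is claimed.
* The improvement exclusion rule is a hard threshold; results for
  countries near $-0.05$ depend on measurement error the package cannot
  see.
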