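---
title: "Functional data analysis of feline activity profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional data analysis of feline activity profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actifda)
```

## The measurement model

Collar-mounted omnidirectional accelerometers summarise a cat's movement into
a unit-less "count" per 1-minute epoch, 1440 values per day. Counts are
non-negative, integer and heavily right-skewed: a cat at rest produces long
runs of zeros and small values, while a play bout produces counts in the
hundreds. All analyses therefore work on the `ln(1 + x)` scale, where the
zero floor maps to zero and bursts are compressed, and then average the
transformed values within 5-minute windows to reduce minute-level
variability. The order matters — the log of a 5-minute mean is not the mean
of the logs — and the package applies the transform first, as `preprocess`
functions and a guard test enforce.

Each subject contributes one baseline week: when more than 7 days were
recorded, the first and last days (partial collar wear) are dropped and the
chronologically last 7 complete days are kept. Days are split into weekdays
(Monday-Friday) and weekend days (Saturday-Sunday); any run of 7 consecutive
calendar days yields the 5 + 2 composition that `build_profile()` requires.

Two functional summaries are built per cat on the common 288-point grid
(5-minute bin midpoints, quadrature weight 1/12 hour per point):

* the **activity profile** `Y(t)`, the pointwise mean of the day-type's
  daily log-scale curves; and
* the **intensity profile** `I(t) = Y(t) - Ave(Y)`, where `Ave(Y)` is the
  grand mean over all 7 x 288 values of the week. Intensity is a
  within-cat contrast: positive values mean "more active than is typical for
  this cat", which also absorbs calibration differences between physical
  monitors. The construction makes the day-weighted mean of the intensity
  profiles exactly zero, `(5 mean_t I_wd + 2 mean_t I_we)/7 = 0`, an identity
  the tests assert at 1e-12.

## Functional PCA

`fpca()` decomposes a sample of curves as
`Y_i(t) = mu(t) + sum_k phi_k(t) xi_ik + eps` with eigenfunctions
orthonormal under the quadrature inner product. The covariance is the
*empirical, unsmoothed* sample covariance with a direct symmetric
eigen-decomposition: the curves here are dense (288 points) and complete, so
PACE-style covariance smoothing buys little and adds a tuning parameter. The
number of components is either requested directly or chosen as the smallest
K whose cumulative variance fraction (relative to the full covariance trace,
measurement error included) reaches a threshold. Numerically negative
eigenvalues are clipped to zero when below `1e-10` of the leading eigenvalue
and refused otherwise.

Eigenfunction sign is arbitrary in theory but matters for interpreting
"positively loaded" subjects and for correlating scores across fits, so the
package fixes a reproducible orientation: the integral of each eigenfunction
over the 5-9 h morning window is made non-negative, with the sign of the
first grid point as tie-break. FPCA is fitted separately for weekend and
weekday curves; `score_correlation()` then pairs subjects across the two
fits, which is how the cross-day-type consistency of individual behaviour is
quantified. `modes_of_variation()` returns `mu +/- 2 sqrt(lambda_k) phi_k`.

## Function-on-scalar regression

`fosr()` fits `Y_i(t) = beta_0(t) + sum_p x_ip beta_p(t) + eps_i(t)` with
each coefficient expanded in a cubic B-spline basis (15 functions on
[0, 24], a standard penalized-spline default with a sensitivity hook) under
a second-order difference penalty. Estimation is penalized least squares
over all `n x 288` observations with a working-independence Gaussian
residual model (`eps` iid, variance `sigma^2`); the Kronecker structure of
the problem reduces every fit to a `(P * 15)`-dimensional linear solve.
Smoothing parameters are selected per term by generalized cross-validation
(coordinate descent over a log-spaced grid, two passes).

Covariates are standardized to zero mean and unit SD before fitting, and the
age-by-body-condition interaction is the product of the two standardized
main effects, so all coefficient functions are on the "standard deviations
away from the mean" scale. Standardization uses each model's own subjects.

Within-curve residual dependence — real, since a cat's 288 bins are far from
independent — is deliberately not modelled in the working likelihood.
Instead, uncertainty comes from `bootstrap_ci()`: whole subjects (curve plus
covariates) are resampled with replacement and the model refit, with the
smoothing parameters held at the original fit's values; pointwise 2.5% and
97.5% percentiles give 95% bands. Holding smoothing fixed is standard
practice for resampled refits and keeps publication-scale runs (2000
resamples) cheap; re-selecting smoothing inside each resample would mix
smoothing variability into the bands. A coefficient is reported as
significant over the maximal grid runs where the band excludes zero
(`significance_regions()`). Small-sample caveat: when a covariate takes few
distinct values, resampled designs can be rank-deficient; failed refits are
dropped, and a failure rate above 5% aborts with an error rather than
returning bands built from a biased subset.

## Hypothesis tests

**Mean-curve equality.** `lrt_mean_equality()` compares a null model (the
covariates of the chosen setting) against an alternative that adds a
time-varying group-indicator coefficient. Both fits use the *unpenalized*
fixed 15-dimensional basis, so the null column space is nested in the
alternative's and the working-Gaussian statistic
`Lambda = N log(RSS_0 / RSS_1)` is non-negative by construction — with a
penalty this monotonicity would not hold, which is why smoothing is an
estimation device in `fosr()` but not part of the test statistic. Because
the working likelihood ignores within-curve dependence, `Lambda` is never
referred to a chi-squared: the null distribution is simulated by
residual-curve resampling (null fitted values plus whole residual curves
resampled across subjects, preserving each curve's internal dependence), and
`p = (1 + #{Lambda* >= Lambda}) / (n_sim + 1)`. The four covariate settings
of the study battery (none; age + BCS + interaction; plus total DJD score;
plus total pain score) all run through this one entry point, with Bonferroni
adjustment across the settings of each profile row.

**Paired day-type comparison.** `lrt_paired_daytype()` tests whether
weekend and weekday mean curves coincide within a group using per-subject
difference curves `D_i = weekend_i - weekday_i`; the alternative fits a free
spline mean to `D`, the null fits zero, and the null distribution sign-flips
whole difference curves, which are exchangeable in sign under no day-type
effect. A sign flip leaves `sum(D^2)` unchanged, so only the alternative RSS
is recomputed per draw.

**Distribution equality.** `distribution_test()` implements the
projection-based two-sample procedure: FPCA on the pooled sample (common
mean removed), projection of both groups onto the leading eigenfunctions,
and a rank-based two-sample Anderson-Darling test per component with a
permutation p-value; `ad_two_sample()` exposes the component test directly,
including exact enumeration for small samples. Per-component p-values are
Bonferroni-corrected at `alpha / K` and combined as
`min(K * min_k p_k, 1)`. K is the smallest number of components reaching
the variance threshold (default 95%), capped at `k_max = 10`: on unsmoothed
profiles the threshold alone can demand dozens of near-noise components,
which adds Bonferroni burden without distributional information. The cap is
a truncation-rule choice on a point where reasonable conventions differ;
the Bonferroni combination stays valid for any K. Ties in projected scores
(possible only for degenerate inputs) are broken by seeded jitter of 1e-9
times the data range, keeping the statistic's rank invariance for
continuous data.

## The synthetic cohort generator

`generate_cohort()` emulates the data structure the analysis assumes, so
every stage is testable without the original recordings. Its defaults were
chosen once, as the package's standing study conditions:

* **Templates** (`bimodal_template()`): on the log-count scale, a constant
  baseline 3.2 plus Gaussian bumps — morning (center 7 h, SD 1 h, amplitude
  1.2), evening (20 h, SD 2 h, 0.9) — and a negative overnight trough
  (3.5 h, SD 1.2 h, depth 1.2). This is the simplest smooth family that
  guarantees a bimodal day with a 02:00-05:00 trough, a sharp morning peak
  inside 05:30-09:00 and a broad evening peak. Weekend mornings are delayed
  1.5 h and flattened to 70% amplitude (owners rise later and less
  uniformly); joint-disease templates multiply all excursions by 0.75,
  producing muted peaks *and* shallower troughs rather than a level shift.
  The baseline puts typical counts in the tens, so mean per-minute counts
  land in the range reported for pet cats and the count-rounding error of
  the log scale stays small over most of the day.
* **Between-cat variation**: orthonormalized 24 h/12 h sinusoids with
  eigenvalues (0.5, 0.25, 0.12), giving smooth subject deviations of
  roughly 0.2 log-units — large enough that inter-cat variability dominates
  measurement noise, as it does on real collars. A subject's weekend and
  weekday scores are bivariate Gaussian with correlation 0.6 per component,
  planting a testable cross-day-type consistency.
* **Counts**: per-minute lognormal noise (SD 0.8 on the latent scale) is
  added before inverting the transform, `round(exp(latent + e) - 1)` clipped
  at zero — exactly compatible with the `ln(1 + x)` analysis scale and
  producing the right-skewed integers the device reports. With zero noise
  the only distortion is rounding, bounded by ~`0.5/(1 + count)` on the log
  scale; recovery tests assert < 0.02 where counts reach 25 and < 0.1 where
  they reach 5.
* **Covariates**: ages center on 6 y (healthy) vs 12 y (DJD), body condition
  on the 9-point scale, pain and radiographic scores within their published
  0-80 / 0-200 ranges and correlated with group, so the regressions face the
  confounding the study design implies. The DJD group carries two enrolment
  sub-study labels in 25:58 proportion, which is what the pipeline's pooling
  check exercises. Planted time-varying covariate effects (`beta_spec`) act
  on cohort-standardized covariates and default to zero.

What the generator does **not** emulate: device physics, collar non-wear
gaps, owner schedules as an explicit covariate, day-to-day autocorrelation
beyond the shared subject curve, and treatment periods. Passing tests
therefore demonstrate that the estimators recover structure of this planted
kind at these noise scales — not that any particular real-data finding is
reproduced.

## Numerical and design choices

* Quartile convention for descriptive summaries: linear interpolation
  (type 7), recorded in the output table.
* Bins are left-closed/right-open, labelled at midpoints; days run
  midnight-to-midnight with no circular wrap of the evening peak.
* Calendar logic is real: day types come from dates, and the generator
  anchors cohorts on a configurable Monday.
* Degenerate inputs fail loudly: zero-variance covariates, zero-variance
  score columns, unknown labels, incomplete days and unpaired subjects are
  labeled errors, and dropped days are logged, never silently repaired.
* Determinism: every stochastic stage takes a seed, the pipeline derives
  per-stage seeds from one master seed, and a rerun under the same
  configuration is byte-identical, artifact by artifact.
* Simulation sizes: headline runs use `n_sim = 10000` null simulations and
  `n_boot = 2000` bootstrap resamples; the pipeline's reduced defaults
  (`n_sim = 200`, `n_boot = 200`, `n_perm = 499`) are the package's
  desk-scale choice for routine reruns, and the test suite uses
  replicate counts (60-500 per Monte-Carlo check) sized to keep binomial
  uncertainty well inside each asserted band.

## Limitations

The mean-curve test's statistic relies on a working-independence
likelihood; its validity comes from the resampling null, not from the
likelihood itself, so reported `Lambda` values are not comparable across
datasets with different dependence structures. The paired and unpaired
day-type comparisons are both provided because study descriptions of such
comparisons are often ambiguous about pairing; the pipeline uses the paired
version. Per-model covariate standardization means coefficient functions
from models fitted on different subject subsets are on slightly different
scales. No imputation is attempted for sub-day non-wear; incomplete days
are simply excluded.
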