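---
title: "Models and methods behind bptrend"
author: "bptrend maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bptrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Home blood pressure cuffs, like most patient-initiated monitoring devices,
produce *unequally spaced repeated measures*: each subject takes readings at
self-chosen times, so the lag between consecutive observations ranges from
minutes to weeks, and it differs between and within subjects.  The question
the package answers is deceptively simple — *was the measure changing over
the course of the study?* — but the irregular sampling breaks the classical
repeated-measures toolkit, which assumes a common visit schedule.

bptrend addresses this with three complementary analyses: a population
mixed model with continuous-time residual correlation, a multiple N-of-1
analysis that treats each subject as their own trial, and a sequential
engine that re-runs either analysis on cumulative monthly slices of the
accruing data.

## The population model

For subject $i$ with $n_i$ readings, we model

$$\mathbf{Y} = \mathbf{X\beta} + \mathbf{Zu} + \mathbf{e},$$

where $\mathbf{X}$ holds an intercept, time since the subject's enrollment
(scaled so one unit is the nominal study period, 182.5 days by default),
and indicator columns for hour of day; $\mathbf{Z}$ maps rows to subjects
and $\mathbf{u} \sim N(0, \sigma^2_u \mathbf{I})$ is a random intercept per
subject; and $\mathbf{e}$ has block-diagonal covariance $\mathbf{R}$.  The
marginal covariance $\mathbf{V} = \mathbf{ZGZ}^\top + \mathbf{R}$ is block
diagonal by subject, which the likelihood code exploits: nothing bigger
than one subject's block is ever factorised.

The hour-of-day covariate absorbs the diurnal blood pressure rhythm.  It
enters as a categorical effect with up to 24 levels; levels nobody used
are dropped and the lowest observed hour is the reference.  Because a
random intercept already absorbs static subject covariates (baseline BMI,
sex, treatment), no further covariates are modelled.

The null hypothesis of interest is $H_0: \beta_{\text{time}} = 0$.

### Residual covariance families

Three structures for a subject's residual block $\Sigma_R$ are supported,
deliberately minimal because $\mathbf{V}$ is large:

* **CS** (compound symmetry): $\Sigma_R = \sigma^2 \mathbf{I}$.  With the
  random intercept this gives equal correlation
  $\sigma^2_u / (\sigma^2_u + \sigma^2)$ between any two readings of a
  subject, regardless of how far apart they are.
* **AR1**: $(\Sigma_R)_{jk} = \sigma^2 \rho^{|j-k|}$ by measurement
  *order*.  Correlation decays with position, not with elapsed time — a
  mis-specification when gaps vary, but a robust workhorse.
* **SP** (spatial power law): $(\Sigma_R)_{jk} = \sigma^2
  \rho^{|t_j - t_k| / \ell}$ with lag unit $\ell$ (1 day by default, so
  $\rho$ is the residual correlation of two readings a day apart).  This
  is the continuous-time generalisation of AR1 and reduces to it exactly
  when readings are equally spaced at one lag unit — an identity the test
  suite asserts to $10^{-8}$.

The SP exponent is measured in days independently of the fixed-effect
time scaling; the two scales serve different purposes (correlation decays
on a day scale, the trend is reported on a study scale) and both are
configurable.

### Why merging is a precondition for SP

When two readings are minutes apart, their SP correlation is nearly 1, two
rows of $\Sigma_R$ become nearly identical, and the block is numerically
singular: the fit either fails or produces garbage.  `check_singularity()`
quantifies this with the reciprocal condition number of each subject's
correlation block, probing at $\rho = 0.2$/day — the magnitude typically
fitted on day-scale series — with a default threshold of $10^{-3}$.  On
generated cohorts this separates cleanly: blocks containing minute-apart
pairs fall one to two orders of magnitude below the threshold, while
blocks whose shortest lag is an hour sit one order above it.
`fit_mixed(kind = "SP")` refuses flagged data unless forced.

`merge_close_readings()` removes the problem rather than flagging it:
readings are clustered greedily in time order — a reading joins the
current cluster while its gap to the cluster's most recent member is
below the window (1 hour by default) — and each cluster is replaced by
the arithmetic mean of its values at the arithmetic mean of its times.
Chained clustering was chosen over first-member anchoring because it is
the simplest deterministic rule; the mean timestamp preserves the
cluster's centroid for later lag computations.  Merging is idempotent and
every surviving within-subject lag is at least the window, both asserted
as properties in the tests.

### Estimation and inference

Variance parameters are estimated by restricted maximum likelihood.  The
implementation profiles twice: the fixed effects are replaced by their
generalised-least-squares solution at each step, and the overall scale
$\sigma^2$ has a closed-form optimum given the variance ratio
$\lambda = \sigma^2_u/\sigma^2$ and $\rho$, so the numerical search runs
over only one (CS) or two (AR1/SP) transformed parameters —
$\log\lambda$, plus $\rho$ on a logistic scale for SP ($\rho \in (0,1)$;
fractional powers of a negative base are undefined) or an
inverse-hyperbolic-tangent scale for AR1 ($\rho \in (-1,1)$).  The
Nelder–Mead (two-parameter) or Brent (one-parameter) search uses relative
tolerance $10^{-10}$, at most 500 iterations, and is restarted from
$\rho \in \{0.1, 0.3, 0.6\}$ with the best optimum kept, so a fit is
deterministic given data and options.  Per-block lag matrices are
computed once per fit and reused across likelihood evaluations.

Model fit is compared by $\mathrm{AIC} = -2\ell_R + 2q$ and
$\mathrm{BIC} = -2\ell_R + q \log m$, counting only the $q$ covariance
parameters (2 for CS, 3 for AR1/SP) against the number of subjects $m$.

Inference on $\beta_{\text{time}}$ is Wald-normal: the 95% interval is
the estimate $\pm 1.96$ standard errors and the p-value refers
estimate/SE to $N(0,1)$.  With thousands of observations and a handful of
fixed effects the small-sample degrees-of-freedom corrections
(Satterthwaite, Kenward–Roger) would change nothing material; they are
deliberately out of scope and the documentation says so rather than
approximating them badly.

## Multiple N-of-1 analysis

`fit_subject()` regresses one subject's values on scaled time plus that
subject's observed hour levels by ordinary least squares, reporting the
slope, its t-test p-value, and the direction.  Cross-subject aggregation
(`summarize_slopes()`) offers three weightings — unweighted,
$\sqrt{n_i}$, and inverse variance $1/\mathrm{SE}_i^2$ — because which
one a given report used is often ambiguous; all three are always
computed.  Uncertainty comes from a percentile bootstrap that resamples
*subjects* with replacement (10,000 replicates by default, seeded and
recorded), since subjects, not readings, are the exchangeable units.

The direction counts feed an exact two-sided binomial sign test of
$P(\text{decrease}) = 1/2$, using the minimum-likelihood convention (the
p-value sums the probabilities of all outcomes no more likely than the
observed one — the convention of `binom.test`).  A doubled-one-tail
definition exists and can differ on asymmetric problems; on the symmetric
binomial the two coincide.  Subjects whose fitted slope is numerically
zero are excluded from the counts.

N-of-1 fits run on unmerged data by default: averaging near-duplicate
readings is a numerical necessity of the SP correlation matrix, not of
ordinary least squares.

## Sequential analysis

`cumulative_partitions()` slices a reading set at
$\text{anchor} + k \cdot \text{period}$ for $k = 1, 2, \dots$, with a
30.44-day mean calendar month as the default period, choosing the number
of partitions so the last slice is the full dataset.  The population mode
anchors at the study's first reading; the N-of-1 mode anchors at each
subject's enrollment.  `sequential_population_fit()` refits the mixed
model on every slice and records the earliest partition whose trend is
significant with the final fit's sign; `sequential_nof1()` does the
per-subject analogue with a generalised-least-squares SP fit (the same
REML machinery with the random-intercept term switched off, since a
single subject has no between-subject variation) and summarises how many
of the subjects significant at month six already showed the trend at
month five.

Two caveats are intentional design positions.  First, **no multiplicity
adjustment is applied across looks**: each partition's p-value is
nominal.  The sequential output describes when a conclusion would have
become visible, not a formally valid stopping rule; group-sequential
boundaries (O'Brien–Fleming and kin) are out of scope.  Second, the
per-subject sequential error model (GLS with SP correlation) differs from
the N-of-1 OLS fits, so the two significance counts need not agree — both
are surfaced rather than reconciled.

## The synthetic study generator

`simulate_study()` produces cohorts with known ground truth so every
stage of the pipeline is testable without any external data.  The
defaults describe the standard study the package's tests assume: 38
subjects followed for 183 days each, enrollment staggered over 135 days
(so calendar data span roughly ten and a half months), a target of 165
readings per subject with a between-subject SD of 70, and measurement on
about three active days per week with one morning-heavy session (05–11h,
peaking 07–08h) and one afternoon session (13–22h) per active day.  With
probability 0.09 a session emits repeat readings 2–40 minutes apart, in
clusters of geometric size (61% simple pairs), mimicking users who
re-measure immediately.  Values follow

$$y_{ij} = \beta_0 + u_i + \beta_{\text{time}}\, t_{ij} + h(\text{hour}_{ij}) + e_{ij},$$

with the residuals drawn recursively per subject:
$e_{i1} \sim N(0, \sigma^2)$ and
$e_{ij} = \rho^{\Delta t}\, e_{i,j-1} + N\!\big(0, \sigma^2 (1 - \rho^{2\Delta t})\big)$,
$\Delta t$ in days.  This recursion's exact stationary covariance *is*
the spatial power law, so generator and fitter are consistent by
construction; a Monte-Carlo test compares the empirical covariance of
thousands of simulated blocks to `sigma_sp()` entrywise.

The default variance parameters — $\sigma_u = 12$ mmHg, $\sigma = 9$
mmHg, $\rho = 0.2$/day, $\beta_0 = 130$ mmHg (systolic), hour effects of
amplitude $\pm 3$ mmHg peaking at 07h, $\beta_{\text{time}} = -2$ mmHg
per study period — are *invented* values chosen once as a plausible
hypertensive home-monitoring cohort; they are not estimates from any real
dataset, and recovery tests therefore validate the package's
self-consistency, not fidelity to any particular cohort.  One global seed
drives deterministic per-subject substreams, so enlarging the cohort
leaves existing subjects' data bit-for-bit unchanged.

What the generator does **not** emulate: dropout, compliance reminders,
device error codes, integer rounding of device displays, daylight-saving
shifts, or between-subject heterogeneity in the trend itself (every
subject shares $\beta_{\text{time}}$).  The last point matters when
interpreting per-subject significance counts: in a real cohort
individual slopes can be large and opposite-signed, making many subjects
individually significant, whereas under the shared-slope generator few
subjects are — passing tests show the machinery is correct, not that any
particular cohort will look like the simulation.

## Numerical and degenerate-input choices

* Timestamps are taken at face value in a single time zone; no
  daylight-saving arithmetic is performed.
* Values outside (0, 400) mmHg are physiologically implausible; they are
  flagged and reported but never silently dropped.
* Enrollment anchors default to each subject's first reading; an external
  roster may move them earlier, never later than a reading.
* A subject block whose covariance factorisation fails raises an error
  naming the subject and the remedy (merge) rather than returning NaNs.
* Partitions too small to fit (fewer than 3 readings, fewer than 2
  distinct times, or $n \le p$) are recorded as unfitted, not fatal.
* Ties in model ranking break by BIC, then by fewer covariance
  parameters.

## Problem sizes in the test suite

The package's own checks run entirely on generated data, sized to keep
the full suite fast while leaving the statistical assertions sharp:
oracle comparisons use 3 subjects × 8 readings (dense matrices are cheap
there); invariance and property loops use cohorts of 4–15 subjects;
parameter-recovery and interval-coverage checks use 100 replicates of a
10-subject × 60-reading cohort, a size at which the REML surface is
well-behaved and 100 fits complete in well under a minute; the
type-I-error simulations use 200–400 replicates of small cohorts.  The
full-size default (38 × 165) is exercised once per run in the acceptance
script.

## Known limitations

No random slopes or nested/crossed random effects; no heterogeneous
residual variances; z-based rather than t-based intervals; SP requires
$\rho > 0$ (a genuinely negative day-scale correlation would demand AR1);
the sequential analysis provides description, not error-controlled
stopping; and the merging rule, while deterministic and idempotent, is
one of several defensible conventions — sensitivity to the window is best
assessed by re-running with `window_hours` varied, which the merge report
makes cheap.
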