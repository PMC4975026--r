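# bptrend

Trend analysis for unequally spaced, patient-initiated repeated measures,
with home blood pressure monitoring as the motivating application.

## The problem

Mobile blood pressure cuffs and similar devices record readings whenever
the user decides to take one.  The resulting series are unequally spaced:
lags between consecutive readings on one subject range from two minutes
(an immediate re-measurement) to weeks, and the schedule differs across
subjects.  Asking the basic longitudinal question — *is blood pressure
changing over the study?* — then requires a model that treats
within-subject correlation as a function of real elapsed time, and some
care with the near-duplicate readings that break such models numerically.

`bptrend` provides:

* a **population mixed model** `Y = Xβ + Zu + e` with random subject
  intercepts (`u ~ N(0, σ²_u I)`) and three residual covariance families
  for the within-subject blocks of `R`: compound symmetry (CS),
  first-order autoregressive by measurement order (AR1), and the spatial
  power law (SP), `cor(e_j, e_k) = ρ^|t_j − t_k|`, the continuous-time
  generalisation of AR1.  Fitting is restricted maximum likelihood over
  the block-diagonal structure (dense `V` is never formed); the trend
  test is a Wald z-test of `H₀: β_time = 0`, and models are ranked by
  `AIC = −2ℓ_R + 2q` / `BIC = −2ℓ_R + q·log(m)` with `q` the number of
  covariance parameters and `m` the number of subjects;
* a **merging preprocessor** that averages readings taken within a short
  window (default one hour) of each other — without it, minute-apart
  readings make the SP correlation matrix singular, which
  `check_singularity()` diagnoses via reciprocal condition numbers;
* a **multiple N-of-1 suite**: per-subject least-squares trends adjusted
  for hour of day, exact two-sided sign tests on the direction counts,
  and unweighted / √n-weighted / inverse-variance-weighted mean slopes
  with subject-resampling bootstrap intervals;
* a **sequential engine** that refits either analysis on cumulative
  monthly partitions of the accruing data to show when the final
  conclusion first became visible (nominal p-values; no α-spending);
* a seedable **synthetic study generator** whose recursive residual
  process has the spatial power law as its exact covariance, providing
  ground truth for every stage.

See `vignettes/bptrend-methods.Rmd` for the full model account, parameter
conventions, and design rationale.

## Worked example

```r
library(bptrend)

# a synthetic 38-subject, six-month monitoring study with known truth
study <- simulate_study(sim_config(seed = 42))
study
#> Synthetic monitoring study (ground truth known)
#>   beta_time = -2 mmHg/period, sigma_u = 12, sigma = 9, rho = 0.2/day, seed = 42
#> Reading set: 6097 readings on 38 subject(s)
#>   systolic    6097 readings
#>   span: 2013-08-24 to 2014-06-27

# average near-duplicate readings so the SP model is estimable
res <- merge_close_readings(study$rs, window_hours = 1)
res$report
#> Merge report (window = 1 h): 6097 readings in, 5342 out, 755 absorbed
#>   clusters merged: size 2: 288 (61%) size 3: 114 (24%) ...

fit <- fit_mixed(res$rs, kind = "SP")
fit
#> Mixed model (REML), residual covariance SP
#>   5342 observations on 38 subjects (systolic)
#>   time trend: -2.382 mmHg per study period (95% CI -3.582, -1.181), p = 0.000101
#>   sigma2_u = 109.985, sigma2 = 80.928, rho = 0.215
#>   -2 logLik(REML) = 37297.84, AIC = 37303.84, BIC = 37308.75

summarize_slopes(nof1_fits(study$rs), weighting = "sqrt_n",
                 n_boot = 10000, seed = 42)
#> Slope summary over 38 subjects
#>   mean slope:             -1.460 mmHg per study period
#>   sqrt(n)-weighted mean:  -2.137
#>   inverse-variance mean:  -2.478
#>   95% bootstrap CI (sqrt_n, 10000 reps): (-3.382, -0.838)
#>   directions: 28 decrease, 10 increase, 0 zero; sign test p = 0.0051
```

The mixed model recovers the generating trend (−2 mmHg per study period
inside the interval), the residual day-lag correlation (0.215 vs the true
0.2), and the variance components (σ²_u = 110 vs 144, σ² = 81 vs 81); the
N-of-1 route reaches the same qualitative conclusion from per-subject
slopes alone.  The sequential analysis shows how early the trend was
visible:

```r
seq <- sequential_population_fit(res$rs, kind = "SP")
seq$first_significant
#> [1] 5        # of 11 monthly partitions — six months before study end
```

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
BPT=$(Rscript -e 'cat(system.file("scripts", "bptrend", package = "bptrend"))')
$BPT simulate --n-subjects 38 --seed 1 --out readings.csv
$BPT merge --input readings.csv --out merged.csv --report merge.json
$BPT fit-mixed --input merged.csv --cov sp --out fit.json
$BPT fit-nof1 --input readings.csv --weighting sqrt_n --out nof1.json
$BPT sequential --input merged.csv --mode population --out seq.json
```

All results are written as JSON/CSV with the effective configuration
echoed into each artifact; logs go to standard error.

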