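Package: bptrend
Title: Trend Analysis for Unequally Spaced, Patient-Initiated Blood
    Pressure Monitoring Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hypothesis testing for unequally spaced repeated measures
    from patient-initiated home monitoring devices, centred on blood
    pressure time series.  Provides linear mixed models with random
    subject intercepts and compound-symmetric, first-order
    autoregressive, or spatial power-law residual covariance, fitted by
    restricted maximum likelihood over block-diagonal subject
    structures; a short-lag merging preprocessor that removes the
    near-duplicate readings which make the spatial power-law
    correlation matrix numerically singular; a multiple N-of-1 suite
    (per-subject trend regressions, exact sign tests, weighted slope
    averages with bootstrap confidence intervals); a sequential engine
    that refits models on cumulative monthly data partitions; and a
    seedable generator of realistic synthetic monitoring studies with
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
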