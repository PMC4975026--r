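#' Per-subject trend regression
#'
#' The N-of-1 estimate: ordinary least squares of blood pressure on time
#' since enrollment (study-period units), adjusting for hour of day with
#' the levels that subject actually used.  When the hour indicators make
#' the design rank deficient they are dropped with a warning and the plain
#' regression on time is reported.
#'
#' @param rs A [reading_set()].
#' @param subject Subject identifier; may be omitted when `rs` holds a
#'   single subject.
#' @param measure Optional measure label to subset on.
#' @param scale_days Days per unit of the time covariate.
#' @return An object of class `subject_fit`: list with `subject_id`,
#'   `n_readings`, `slope` (mmHg per study period), `slope_se`, `p_value`
#'   (two-sided t), and `direction` (`"decrease"`, `"increase"` or
#'   `"zero"`).
#' @export
fit_subject <- function(rs, subject = NULL, measure = NULL, scale_days = 182.5) {
  if (!is.null(subject) || !is.null(measure)) {
    rs <- subset_readings(rs, measure = measure, subjects = subject)
  }
  ids <- unique(rs$readings$subject_id)
  if (length(ids) != 1L) {
    stop_config("fit_subject needs a single subject; got ", length(ids))
  }
  r <- rs$readings
  if (nrow(r) < 3L) stop_data("subject ", ids, " has fewer than 3 readings")
  t_scaled <- time_since_enrollment(rs, scale_days = scale_days)
  if (length(unique(t_scaled)) < 2L) {
    stop_data("subject ", ids, " has fewer than 2 distinct reading times")
  }
  hr <- factor(hour_of_day(rs))

  fit <- if (nlevels(hr) > 1L) {
    stats::lm(r$value ~ t_scaled + hr)
  } else {
    stats::lm(r$value ~ t_scaled)
  }
  if (anyNA(stats::coef(fit))) {
    warning("subject ", ids, ": hour covariate aliased with time, dropped")
    fit <- stats::lm(r$value ~ t_scaled)
  }
  sm <- summary(fit)$coefficients
  slope <- sm["t_scaled", "Estimate"]
  pval <- sm["t_scaled", "Pr(>|t|)"]
  if (!is.finite(pval)) pval <- NA_real_  # perfect fit: SE 0, t undefined
  structure(
    list(subject_id = ids,
         n_readings = nrow(r),
         slope = slope,
         slope_se = sm["t_scaled", "Std. Error"],
         p_value = pval,
         direction = {
           # numerically flat fits count as zero, not as a sign
           eps <- 1e-10 * max(1, abs(mean(r$value)))
           if (slope < -eps) "decrease" else if (slope > eps) "increase" else "zero"
         }),
    class = "subject_fit"
  )
}

#' @export
print.subject_fit <- function(x, ...) {
  cat(sprintf("Subject %s: %d readings, slope %.3f mmHg/period (SE %.3f), p = %.3g [%s]\n",
              x$subject_id, x$n_readings, x$slope, x$slope_se, x$p_value,
              x$direction))
  invisible(x)
}

#' Fit every subject individually
#'
#' Runs [fit_subject()] across the cohort and tabulates the results.
#' Subjects with too few readings or times are skipped with a warning.
#'
#' @inheritParams fit_subject
#' @return A data frame with one row per fitted subject: `subject_id`,
#'   `n_readings`, `slope`, `slope_se`, `p_value`, `direction`.
#' @export
nof1_fits <- function(rs, measure = NULL, scale_days = 182.5) {
  if (!is.null(measure)) rs <- subset_readings(rs, measure = measure)
  ids <- rs$enrollment$subject_id
  rows <- list()
  for (id in ids) {
    f <- tryCatch(fit_subject(rs, subject = id, scale_days = scale_days),
                  bptrend_data_error = function(e) {
                    warning("skipping subject ", id, ": ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(f)) rows[[length(rows) + 1L]] <- as.data.frame(unclass(f),
                                                                stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop_data("no subject could be fitted")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact two-sided sign test on slope directions
#'
#' Tests whether decreases and increases are equally likely across
#' subjects: an exact binomial test of `P(decrease) = 1/2` on the subjects
#' with a nonzero slope.  The two-sided p-value follows the minimum-
#' likelihood convention — the sum of the probabilities of all outcomes no
#' more likely than the one observed (the convention of
#' [stats::binom.test()]; a doubled-one-tail definition would give slightly
#' different values).
#'
#' @param n_decrease,n_increase Non-negative counts; not both zero.
#' @return The two-sided p-value.
#' @export
sign_test_exact <- function(n_decrease, n_increase) {
  if (n_decrease < 0 || n_increase < 0) stop_config("counts must be non-negative")
  n <- n_decrease + n_increase
  if (n == 0) stop_data("sign test undefined: no nonzero slopes")
  probs <- stats::dbinom(0:n, n, 0.5)
  # outcomes no more likely than the observed one, with a tolerance for
  # ties in floating point
  sum(probs[probs <= probs[n_decrease + 1L] * (1 + 1e-7)])
}

#' Aggregate per-subject slopes across the cohort
#'
#' Computes the unweighted mean slope, the mean weighted by the square root
#' of each subject's number of readings, and the inverse-variance-weighted
#' mean; counts slope directions with an exact sign test; and attaches a
#' percentile bootstrap confidence interval (resampling subjects with
#' replacement) for the weighting selected by `weighting`.
#'
#' @param fits Data frame from [nof1_fits()] (or a list of `subject_fit`s).
#' @param weighting Which weighted mean the bootstrap interval refers to:
#'   `"sqrt_n"` (default), `"unweighted"` or `"inverse_variance"`.
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed recorded in the output; the bootstrap is
#'   reproducible given it.
#' @param conf_level Interval coverage (default 0.95).
#' @return An object of class `slope_summary`.
#' @export
summarize_slopes <- function(fits, weighting = c("sqrt_n", "unweighted", "inverse_variance"),
                             n_boot = 10000L, seed = 1L, conf_level = 0.95) {
  weighting <- match.arg(weighting)
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- do.call(rbind, lapply(fits, function(f) as.data.frame(unclass(f))))
  }
  if (nrow(fits) < 2L) stop_config("need at least 2 subject fits")
  fits <- fits[order(fits$subject_id), , drop = FALSE]  # order-invariant

  slopes <- fits$slope
  w_sqrt <- sqrt(fits$n_readings)
  se <- fits$slope_se
  usable_iv <- se > 0
  if (!all(usable_iv)) {
    warning(sum(!usable_iv), " subject(s) with zero slope SE excluded from ",
            "the inverse-variance mean")
  }
  wmean <- function(x, w) sum(w * x) / sum(w)

  w_for <- switch(weighting,
                  unweighted = rep(1, length(slopes)),
                  sqrt_n = w_sqrt,
                  inverse_variance = ifelse(usable_iv, 1 / se^2, 0))

  set.seed(seed)
  m <- length(slopes)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(m, m, replace = TRUE)
    wmean(slopes[idx], w_for[idx])
  }, 0)
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 7))

  n_dec <- sum(fits$direction == "decrease")
  n_inc <- sum(fits$direction == "increase")
  structure(
    list(n_subjects = m,
         mean_slope = mean(slopes),
         weighted_mean_slope = wmean(slopes, w_sqrt),
         ivw_mean_slope = wmean(slopes[usable_iv], 1 / se[usable_iv]^2),
         weighting = weighting,
         point_estimate = wmean(slopes, w_for),
         bootstrap_ci = ci,
         n_boot = n_boot, seed = seed, conf_level = conf_level,
         n_decrease = n_dec, n_increase = n_inc,
         n_zero = m - n_dec - n_inc,
         sign_test_p = if (n_dec + n_inc > 0) sign_test_exact(n_dec, n_inc) else NA_real_),
    class = "slope_summary"
  )
}

#' @export
print.slope_summary <- function(x, ...) {
  cat(sprintf("Slope summary over %d subjects\n", x$n_subjects))
  cat(sprintf("  mean slope:            %7.3f mmHg per study period\n", x$mean_slope))
  cat(sprintf("  sqrt(n)-weighted mean: %7.3f\n", x$weighted_mean_slope))
  cat(sprintf("  inverse-variance mean: %7.3f\n", x$ivw_mean_slope))
  cat(sprintf("  %d%% bootstrap CI (%s, %d reps): (%.3f, %.3f)\n",
              round(100 * x$conf_level), x$weighting, x$n_boot,
              x$bootstrap_ci[1L], x$bootstrap_ci[2L]))
  cat(sprintf("  directions: %d decrease, %d increase, %d zero; sign test p = %.3g\n",
              x$n_decrease, x$n_increase, x$n_zero, x$sign_test_p))
  invisible(x)
}
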