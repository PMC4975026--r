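#' Cumulative monthly data partitions
#'
#' Splits a reading set into nested cumulative partitions: partition `k`
#' contains every reading taken before `anchor + k * period_days`.  The
#' number of partitions is chosen so the last one always equals the full
#' dataset.  In population mode the anchor is the earliest reading in the
#' dataset; in subject mode each subject is anchored at their own
#' enrollment (used by [sequential_nof1()]).
#'
#' @param rs A [reading_set()].
#' @param period_days Period length in days; default 30.44, the mean
#'   calendar month.
#' @param anchor `"study"` (one shared anchor) or `"subject"`.
#' @return In `"study"` mode, a list of [reading_set()]s (class
#'   `partition_list`, with cutoffs as attribute).  In `"subject"` mode, a
#'   list per subject of such lists.
#' @export
cumulative_partitions <- function(rs, period_days = 30.44,
                                  anchor = c("study", "subject")) {
  anchor <- match.arg(anchor)
  if (!is.numeric(period_days) || period_days <= 0) {
    stop_config("period_days must be positive")
  }
  if (anchor == "subject") {
    return(lapply(stats::setNames(rs$enrollment$subject_id,
                                  rs$enrollment$subject_id), function(id) {
      cumulative_partitions(subset_readings(rs, subjects = id),
                            period_days = period_days, anchor = "study")
    }))
  }
  a <- min(rs$readings$timestamp)
  span_days <- days_between(max(rs$readings$timestamp), a)
  k_max <- floor(span_days / period_days) + 1L
  cutoffs <- a + as.difftime(seq_len(k_max) * period_days, units = "days")
  parts <- lapply(cutoffs, function(cut) subset_readings(rs, before = cut))
  attr(parts, "cutoffs") <- cutoffs
  attr(parts, "period_days") <- period_days
  class(parts) <- "partition_list"
  parts
}

#' @export
print.partition_list <- function(x, ...) {
  cat(sprintf("%d cumulative partitions (period %.2f days)\n",
              length(x), attr(x, "period_days")))
  for (k in seq_along(x)) {
    cat(sprintf("  %2d: up to %s, %d readings, %d subjects\n", k,
                format(attr(x, "cutoffs")[k], "%Y-%m-%d"),
                n_readings(x[[k]]), n_subjects(x[[k]])))
  }
  invisible(x)
}

#' Sequential population analysis over cumulative partitions
#'
#' Refits the population mixed model on each cumulative monthly partition,
#' mimicking an analysis that is re-run as data accrue, and records when
#' the final conclusion (a nonzero time trend of the final fit's sign at
#' level `alpha`) first becomes visible.  No multiplicity adjustment is
#' applied across looks — each partition's p-value is nominal, which is a
#' deliberate caveat of this design.
#'
#' @param rs A merged [reading_set()] holding one measure.
#' @param kind Residual covariance family for each fit (default `"SP"`).
#' @param alpha Significance level.
#' @param period_days Partition period, days.
#' @param measure Optional measure to subset on.
#' @param ... Passed to [fit_mixed()].
#' @return An object of class `sequential_result`: a per-partition data
#'   frame (`partition`, `cutoff`, `n_readings`, `n_subjects`, `estimate`,
#'   `ci_lower`, `ci_upper`, `p_value`, `converged`, `significant`) plus
#'   `first_significant` — the earliest partition significant with the
#'   final fit's sign.
#' @export
sequential_population_fit <- function(rs, kind = "SP", alpha = 0.05,
                                      period_days = 30.44, measure = NULL, ...) {
  if (!is.null(measure)) rs <- subset_readings(rs, measure = measure)
  parts <- cumulative_partitions(rs, period_days = period_days)
  rows <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    fit <- tryCatch(fit_mixed(parts[[k]], kind = kind, ...),
                    error = function(e) NULL)
    rows[[k]] <- data.frame(
      partition = k,
      cutoff = attr(parts, "cutoffs")[k],
      n_readings = n_readings(parts[[k]]),
      n_subjects = n_subjects(parts[[k]]),
      estimate = if (is.null(fit)) NA_real_ else fit$beta_time$estimate,
      ci_lower = if (is.null(fit)) NA_real_ else fit$beta_time$ci_lower,
      ci_upper = if (is.null(fit)) NA_real_ else fit$beta_time$ci_upper,
      p_value = if (is.null(fit)) NA_real_ else fit$beta_time$p_value,
      converged = !is.null(fit) && fit$converged
    )
  }
  tab <- do.call(rbind, rows)
  final_sign <- sign(tab$estimate[nrow(tab)])
  tab$significant <- !is.na(tab$p_value) & tab$p_value < alpha &
    sign(tab$estimate) == final_sign
  first_sig <- if (any(tab$significant)) min(tab$partition[tab$significant]) else NA_integer_
  structure(
    list(table = tab, first_significant = first_sig, alpha = alpha,
         kind = kind, period_days = period_days),
    class = "sequential_result"
  )
}

#' @export
print.sequential_result <- function(x, ...) {
  cat(sprintf("Sequential analysis (%s covariance, alpha = %g, period %.2f d)\n",
              x$kind, x$alpha, x$period_days))
  tab <- x$table
  tab$cutoff <- format(tab$cutoff, "%Y-%m-%d")
  print.data.frame(tab, digits = 4, row.names = FALSE)
  if (!is.na(x$first_significant)) {
    cat(sprintf("First partition significant with the final sign: %d of %d\n",
                x$first_significant, nrow(tab)))
  } else {
    cat("No partition reached significance with the final sign.\n")
  }
  invisible(x)
}

# Per-subject generalised-least-squares trend fit with SP-correlated
# errors: the population machinery with the random intercept omitted.
fit_subject_gls <- function(rs_subject, scale_days = 182.5, lag_unit_days = 1,
                            control = list()) {
  dm <- build_design(rs_subject, scale_days = scale_days)
  fit_mixed_design(dm, kind = "SP", lag_unit_days = lag_unit_days,
                   control = control, with_random_intercept = FALSE)
}

#' Sequential N-of-1 analysis
#'
#' For each subject, partitions that subject's readings into cumulative
#' monthly blocks anchored at their enrollment, and refits the subject's
#' trend on each block by generalised least squares with spatial power-law
#' correlated errors (no between-subject term).  The summary asks: of the
#' subjects with a significant trend at month `month_final`, how many
#' already showed it at month `month_final - 1`?
#'
#' @param rs A [reading_set()] holding one measure (subset with `measure`).
#' @param alpha Significance level.
#' @param period_days Partition period, days.
#' @param measure Optional measure label.
#' @param month_final Partition index counted as "study end" for the
#'   early-detection summary (default 6, a six-month enrollment).
#' @param scale_days,lag_unit_days As in [fit_mixed()].
#' @param min_readings Minimum readings for a partition to be fitted.
#' @return An object of class `sequential_nof1_result`: per-subject,
#'   per-partition data frame plus the early-detection counts
#'   `n_significant_final` and `n_early` (already significant one month
#'   earlier).
#' @export
sequential_nof1 <- function(rs, alpha = 0.05, period_days = 30.44,
                            measure = NULL, month_final = 6L,
                            scale_days = 182.5, lag_unit_days = 1,
                            min_readings = 3L) {
  if (!is.null(measure)) rs <- subset_readings(rs, measure = measure)
  rows <- list()
  for (id in rs$enrollment$subject_id) {
    sub <- subset_readings(rs, subjects = id)
    parts <- cumulative_partitions(sub, period_days = period_days)
    for (k in seq_along(parts)) {
      pk <- parts[[k]]
      enough <- n_readings(pk) >= min_readings &&
        length(unique(pk$readings$timestamp)) >= 2L
      fit <- if (enough) {
        tryCatch(fit_subject_gls(pk, scale_days = scale_days,
                                 lag_unit_days = lag_unit_days),
                 error = function(e) NULL)
      } else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, partition = k,
        n_readings = n_readings(pk),
        estimate = if (is.null(fit)) NA_real_ else fit$beta_time$estimate,
        p_value = if (is.null(fit)) NA_real_ else fit$beta_time$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  tab$significant <- !is.na(tab$p_value) & tab$p_value < alpha

  at <- function(k) tab[tab$partition == k & tab$significant, ]
  fin <- at(month_final)
  prev <- at(month_final - 1L)
  # early detection requires the same trend direction a month earlier
  early_ids <- intersect(fin$subject_id, prev$subject_id)
  early_ids <- early_ids[vapply(early_ids, function(id) {
    sign(fin$estimate[fin$subject_id == id]) ==
      sign(prev$estimate[prev$subject_id == id])
  }, TRUE)]
  structure(
    list(table = tab,
         month_final = month_final,
         n_significant_final = nrow(fin),
         n_early = length(early_ids),
         early_subjects = early_ids,
         alpha = alpha, period_days = period_days),
    class = "sequential_nof1_result"
  )
}

#' @export
print.sequential_nof1_result <- function(x, ...) {
  cat(sprintf("Sequential N-of-1 analysis (alpha = %g)\n", x$alpha))
  cat(sprintf("  %d subject(s) significant at month %d; %d of them already at month %d\n",
              x$n_significant_final, x$month_final, x$n_early, x$month_final - 1L))
  invisible(x)
}
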