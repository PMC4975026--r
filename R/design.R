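#' Build model matrices for the repeated-measures mixed model
#'
#' Constructs the response vector and fixed-effects design for
#' `Y = X beta + Z u + e`: an intercept, time since enrollment in
#' study-period units, and indicator columns for hour of day.  The hour
#' covariate has up to 24 levels; levels with no observations are omitted
#' and the lowest observed hour is the reference.  `Z` (random subject
#' intercepts) is not materialised — the per-subject row blocks carry the
#' same information and the likelihood is evaluated block-diagonally.
#'
#' @param rs A [reading_set()] holding a single measure (subset first with
#'   [subset_readings()] if needed).
#' @param scale_days Days per unit of the time covariate (default 182.5,
#'   the nominal six-month study period).
#' @param measure Optional measure label used to subset `rs` first.
#' @return An object of class `design_matrices`: list with `Y`, `X`,
#'   `times` (days since each subject's first reading, for the residual
#'   covariance), `subject` (factor), `blocks` (row-index list per subject),
#'   `hours_used`, `scale_days`, `n`, `p`.
#' @export
build_design <- function(rs, scale_days = 182.5, measure = NULL) {
  if (!is.null(measure)) rs <- subset_readings(rs, measure = measure)
  r <- rs$readings
  if (!nrow(r)) stop_data("empty reading set")
  if (length(unique(r$measure)) > 1L) {
    stop_config("reading set holds multiple measures (",
                paste(unique(r$measure), collapse = ", "),
                "); pass measure= to select one")
  }

  t_scaled <- time_since_enrollment(rs, scale_days = scale_days)
  hr <- hour_of_day(rs)
  hours_used <- sort(unique(hr))

  X <- cbind(`(Intercept)` = 1, time = t_scaled)
  if (length(hours_used) > 1L) {
    # reference level: lowest observed hour
    for (h in hours_used[-1L]) {
      X <- cbind(X, as.numeric(hr == h))
      colnames(X)[ncol(X)] <- sprintf("hour%02d", h)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    warning("dropping aliased design column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }

  subject <- factor(r$subject_id, levels = unique(r$subject_id))
  blocks <- split(seq_len(nrow(r)), subject)
  first_ts <- vapply(blocks, function(i) as.numeric(r$timestamp[i[1L]]), 0)
  times <- days_between(r$timestamp,
                        as.POSIXct(first_ts[as.integer(subject)],
                                   origin = "1970-01-01", tz = "UTC"))

  structure(
    list(Y = r$value, X = X, times = times, subject = subject,
         blocks = blocks, hours_used = hours_used,
         scale_days = scale_days, n = nrow(r), p = ncol(X),
         measure = r$measure[1L]),
    class = "design_matrices"
  )
}

#' @export
print.design_matrices <- function(x, ...) {
  cat(sprintf("Design: %d observations, %d subjects, %d fixed-effect columns\n",
              x$n, length(x$blocks), x$p))
  cat(sprintf("  hour-of-day levels observed: %d (reference %02d:00)\n",
              length(x$hours_used), x$hours_used[1L]))
  invisible(x)
}
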