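#' Merge near-duplicate readings taken within a short window
#'
#' Patient-initiated devices occasionally record two or more readings within
#' minutes of each other.  Under a spatial power-law residual correlation
#' those near-zero lags drive pairs of rows of the within-subject
#' correlation matrix towards equality, making it numerically singular and
#' the model unfittable.  This preprocessor replaces each cluster of
#' close-in-time readings by a single averaged reading.
#'
#' Clustering is greedy and chained in time order: a reading joins the
#' current cluster when its gap to the cluster's most recent member is
#' strictly less than `window_hours`; otherwise it starts a new cluster.
#' Each cluster becomes one reading whose value and timestamp are the
#' arithmetic means of its members.  Merging is applied within each subject
#' and measure independently.
#'
#' The output is idempotent: every consecutive within-subject lag after
#' merging is at least `window_hours`, so a second pass changes nothing.
#'
#' @param rs A [reading_set()], time-sorted (as the constructor guarantees).
#' @param window_hours Positive merge window, hours.  Default 1.
#' @return A list with elements `rs` (the merged [reading_set()]) and
#'   `report` (a `merge_report`: window, input/output counts, number of
#'   readings absorbed into averages, and a cluster-size histogram).
#' @export
merge_close_readings <- function(rs, window_hours = 1) {
  if (!is.numeric(window_hours) || length(window_hours) != 1L || window_hours <= 0) {
    stop_config("window_hours must be a single positive number")
  }
  r <- rs$readings
  key <- paste(r$subject_id, r$measure, sep = "\r")
  secs <- as.numeric(r$timestamp)

  # chained clustering: new cluster when gap to previous reading >= window
  gap_h <- c(Inf, diff(secs)) / 3600
  new_cluster <- gap_h >= window_hours | c(TRUE, key[-1L] != key[-length(key)])
  cid <- cumsum(new_cluster)

  sizes0 <- tabulate(cid)
  agg_val <- rowsum(r$value, cid)[, 1L] / sizes0
  agg_ts <- rowsum(secs, cid)[, 1L] / sizes0
  first_idx <- which(new_cluster)
  merged <- data.frame(
    subject_id = r$subject_id[first_idx],
    timestamp = as.POSIXct(as.numeric(agg_ts), origin = "1970-01-01",
                           tz = attr(r$timestamp, "tzone") %||% "UTC"),
    value = as.numeric(agg_val),
    measure = r$measure[first_idx],
    stringsAsFactors = FALSE
  )

  hist <- table(sizes0)
  report <- structure(
    list(window = window_hours,
         n_input = nrow(r),
         n_output = nrow(merged),
         n_merged_away = nrow(r) - nrow(merged),
         cluster_size_histogram = stats::setNames(as.integer(hist), names(hist))),
    class = "merge_report"
  )

  out <- suppressWarnings(reading_set(merged, enrollment = rs$enrollment))
  out$study_start <- rs$study_start
  list(rs = out, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf("Merge report (window = %g h): %d readings in, %d out, %d absorbed\n",
              x$window, x$n_input, x$n_output, x$n_merged_away))
  h <- x$cluster_size_histogram
  multi <- h[names(h) != "1"]
  if (length(multi) && sum(multi) > 0) {
    cat("  clusters merged:")
    for (s in names(multi)) {
      cat(sprintf(" size %s: %d (%.0f%%)", s, multi[[s]],
                  100 * multi[[s]] / sum(multi)))
    }
    cat("\n")
  }
  invisible(x)
}

#' Write a merge report as JSON
#' @param report A `merge_report` from [merge_close_readings()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_merge_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Within-subject lags between consecutive readings
#'
#' @param rs A [reading_set()].
#' @return Numeric vector of lags in hours between consecutive readings on
#'   the same subject and measure.  Subjects with a single reading
#'   contribute nothing.
#' @export
consecutive_lags <- function(rs) {
  r <- rs$readings
  key <- paste(r$subject_id, r$measure, sep = "\r")
  secs <- as.numeric(r$timestamp)
  lag_h <- diff(secs) / 3600
  same <- key[-1L] == key[-length(key)]
  lag_h[same]
}

#' Histogram of lags between consecutive within-subject readings
#'
#' Short lags (minutes) are the readings that the spatial power-law model
#' cannot tolerate; this histogram shows how common they are before and
#' after [merge_close_readings()].
#'
#' @param rs A [reading_set()].
#' @param bin_hours Positive bin width in hours.
#' @return A data frame with columns `bin_lo`, `bin_hi` and `count`; the
#'   raw lags are attached as attribute `"lags"`.
#' @export
lag_histogram <- function(rs, bin_hours = 1) {
  if (!is.numeric(bin_hours) || bin_hours <= 0) {
    stop_config("bin_hours must be positive")
  }
  lags <- consecutive_lags(rs)
  if (!length(lags)) {
    out <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0), count = integer(0))
    attr(out, "lags") <- lags
    return(out)
  }
  bin <- floor(lags / bin_hours)
  tab <- table(bin)
  out <- data.frame(
    bin_lo = as.numeric(names(tab)) * bin_hours,
    bin_hi = (as.numeric(names(tab)) + 1) * bin_hours,
    count = as.integer(tab)
  )
  attr(out, "lags") <- lags
  out
}
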