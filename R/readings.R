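#' Construct a validated set of device readings
#'
#' A `reading_set` is the central data container of the package: a
#' long-format table of timestamped measurements (one row per reading),
#' grouped by subject and sorted by time within subject, together with an
#' enrollment anchor per subject and the overall study start.  All model
#' fitting, merging and partitioning functions consume this class.
#'
#' @param readings A data frame with columns `subject_id` (character),
#'   `timestamp` (`POSIXct` or ISO 8601 character), `value` (mmHg, positive
#'   numeric) and `measure` (`"systolic"` or `"diastolic"`).
#' @param enrollment Optional data frame with columns `subject_id` and
#'   `enrollment_time` supplying external enrollment anchors.  When omitted,
#'   each subject's earliest reading is used.
#' @param tz Time zone in which character timestamps are interpreted.
#'   Readings are taken at face value in a single zone; no daylight-saving
#'   arithmetic is applied.
#'
#' @details Values outside the physiologic screen (0, 400) mmHg are flagged
#'   in the `flagged` column and reported with a warning, never silently
#'   dropped.  An enrollment anchor later than one of the subject's readings
#'   is an error: time since enrollment must be non-negative.
#'
#' @return An object of class `reading_set`: a list with elements
#'   `readings` (the validated, sorted data frame), `enrollment`
#'   (one row per subject) and `study_start` (earliest timestamp overall).
#' @seealso [load_readings()], [merge_close_readings()],
#'   [time_since_enrollment()]
#' @export
reading_set <- function(readings, enrollment = NULL, tz = "UTC") {
  required <- c("subject_id", "timestamp", "value")
  missing_cols <- setdiff(required, names(readings))
  if (length(missing_cols)) {
    stop_config("readings is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  readings <- as.data.frame(readings, stringsAsFactors = FALSE)
  readings$subject_id <- as.character(readings$subject_id)
  if (is.null(readings$measure)) readings$measure <- "unspecified"
  readings$measure <- as.character(readings$measure)

  ts <- parse_timestamps(readings$timestamp, tz = tz)
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop_data("unparseable timestamp(s) in row(s): ",
              paste(utils::head(bad, 10L), collapse = ", "),
              if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L) else "")
  }
  readings$timestamp <- ts
  readings$value <- as.numeric(readings$value)
  if (anyNA(readings$value)) {
    stop_data("non-numeric value(s) in row(s): ",
              paste(utils::head(which(is.na(readings$value)), 10L), collapse = ", "))
  }

  # physiologic screen: flag, never drop
  readings$flagged <- !(readings$value > 0 & readings$value < 400)
  if (any(readings$flagged)) {
    warning(sprintf("%d reading(s) outside the physiologic range (0, 400) mmHg flagged (rows %s)",
                    sum(readings$flagged),
                    paste(utils::head(which(readings$flagged), 10L), collapse = ", ")))
  }

  ord <- order(readings$subject_id, readings$measure, readings$timestamp)
  readings <- readings[ord, , drop = FALSE]
  rownames(readings) <- NULL

  first_ts <- tapply(as.numeric(readings$timestamp), readings$subject_id, min)
  subjects <- names(first_ts)
  if (is.null(enrollment)) {
    enrollment <- data.frame(
      subject_id = subjects,
      enrollment_time = as.POSIXct(as.numeric(first_ts),
                                   origin = "1970-01-01", tz = tz),
      stringsAsFactors = FALSE
    )
  } else {
    enrollment <- as.data.frame(enrollment, stringsAsFactors = FALSE)
    if (!all(c("subject_id", "enrollment_time") %in% names(enrollment))) {
      stop_config("enrollment must have columns subject_id and enrollment_time")
    }
    enrollment$subject_id <- as.character(enrollment$subject_id)
    enrollment$enrollment_time <- parse_timestamps(enrollment$enrollment_time, tz = tz)
    orphan <- setdiff(enrollment$subject_id, subjects)
    if (length(orphan)) {
      warning("enrollment roster lists subject(s) with zero readings, excluded: ",
              paste(orphan, collapse = ", "))
      enrollment <- enrollment[enrollment$subject_id %in% subjects, , drop = FALSE]
    }
    uncovered <- setdiff(subjects, enrollment$subject_id)
    if (length(uncovered)) {
      enrollment <- rbind(enrollment, data.frame(
        subject_id = uncovered,
        enrollment_time = as.POSIXct(as.numeric(first_ts[uncovered]),
                                     origin = "1970-01-01", tz = tz),
        stringsAsFactors = FALSE
      ))
    }
    anchor <- enrollment$enrollment_time[match(readings$subject_id, enrollment$subject_id)]
    if (any(anchor > readings$timestamp)) {
      stop_data("enrollment_time later than a reading for subject(s): ",
                paste(unique(readings$subject_id[anchor > readings$timestamp]), collapse = ", "))
    }
  }
  enrollment <- enrollment[order(enrollment$subject_id), , drop = FALSE]
  rownames(enrollment) <- NULL

  structure(
    list(readings = readings,
         enrollment = enrollment,
         study_start = min(readings$timestamp)),
    class = "reading_set"
  )
}

#' @export
print.reading_set <- function(x, ...) {
  r <- x$readings
  cat(sprintf("Reading set: %d readings on %d subject(s)\n",
              nrow(r), nrow(x$enrollment)))
  for (m in unique(r$measure)) {
    cat(sprintf("  %-10s %5d readings\n", m, sum(r$measure == m)))
  }
  cat(sprintf("  span: %s to %s\n",
              format(min(r$timestamp), "%Y-%m-%d"),
              format(max(r$timestamp), "%Y-%m-%d")))
  if (any(r$flagged)) cat(sprintf("  %d flagged reading(s)\n", sum(r$flagged)))
  invisible(x)
}

#' Number of readings and subjects
#' @param rs A [reading_set()].
#' @return `n_readings()` the number of rows; `n_subjects()` the number of
#'   distinct subjects.
#' @export
n_readings <- function(rs) nrow(rs$readings)

#' @rdname n_readings
#' @export
n_subjects <- function(rs) nrow(rs$enrollment)

#' Restrict a reading set to one measure or a subset of subjects
#'
#' @param rs A [reading_set()].
#' @param measure Optional measure label to keep.
#' @param subjects Optional character vector of subject ids to keep.
#' @param before Optional `POSIXct` cutoff; readings at or after it are
#'   dropped (used by the sequential engine).
#' @return A new `reading_set` (enrollment anchors are carried over).
#' @export
subset_readings <- function(rs, measure = NULL, subjects = NULL, before = NULL) {
  r <- rs$readings
  keep <- rep(TRUE, nrow(r))
  if (!is.null(measure)) keep <- keep & r$measure %in% measure
  if (!is.null(subjects)) keep <- keep & r$subject_id %in% subjects
  if (!is.null(before)) keep <- keep & r$timestamp < before
  r <- r[keep, , drop = FALSE]
  if (!nrow(r)) stop_data("no readings left after subsetting")
  enr <- rs$enrollment[rs$enrollment$subject_id %in% unique(r$subject_id), , drop = FALSE]
  out <- structure(
    list(readings = r, enrollment = enr, study_start = rs$study_start),
    class = "reading_set"
  )
  rownames(out$readings) <- NULL
  rownames(out$enrollment) <- NULL
  out
}

#' Load device readings from a long-format CSV file
#'
#' Reads a comma-separated file (header row required, UTF-8) holding one
#' device reading per row and returns a validated [reading_set()].  Because
#' exported device data rarely share a column layout, a `column_map` names
#' the columns holding each field.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping the canonical fields
#'   `subject_id`, `timestamp`, `value` (and optionally `measure`) to the
#'   column names actually present in the file.
#' @param measure Measure label (`"systolic"` or `"diastolic"`) applied to
#'   every row when the file has no measure column.
#' @param enrollment Optional enrollment roster, see [reading_set()].
#' @param drop_invalid If `TRUE`, rows with unparseable timestamps or
#'   non-numeric values are reported (with their row numbers) and excluded;
#'   if `FALSE` (default) they raise a data error.
#' @param tz Time zone for character timestamps.
#' @return A [reading_set()].
#' @export
load_readings <- function(path,
                          column_map = c(subject_id = "subject_id",
                                         timestamp = "timestamp",
                                         value = "value"),
                          measure = NULL,
                          enrollment = NULL,
                          drop_invalid = FALSE,
                          tz = "UTC") {
  if (!file.exists(path)) stop_config("input file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("subject_id", "timestamp", "value")
  if (!all(needed %in% names(column_map))) {
    stop_config("column_map must name subject_id, timestamp and value")
  }
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent)) {
    stop_config("mapped column(s) not present in ", path, ": ",
                paste(absent, collapse = ", "))
  }
  df <- data.frame(
    subject_id = as.character(raw[[column_map[["subject_id"]]]]),
    timestamp = raw[[column_map[["timestamp"]]]],
    value = raw[[column_map[["value"]]]],
    stringsAsFactors = FALSE
  )
  df$measure <- if ("measure" %in% names(column_map)) {
    as.character(raw[[column_map[["measure"]]]])
  } else {
    measure %||% "unspecified"
  }

  if (drop_invalid) {
    ts <- parse_timestamps(df$timestamp, tz = tz)
    val <- suppressWarnings(as.numeric(df$value))
    bad <- which(is.na(ts) | is.na(val))
    if (length(bad)) {
      warning(sprintf("dropping %d invalid row(s): %s", length(bad),
                      paste(utils::head(bad, 10L), collapse = ", ")))
      df <- df[-bad, , drop = FALSE]
    }
  }
  reading_set(df, enrollment = enrollment, tz = tz)
}

#' Write a reading set back to CSV
#'
#' Emits the canonical long schema `subject_id, timestamp, value, measure`
#' (ISO 8601 timestamps), so merged data can round-trip through
#' [load_readings()].
#'
#' @param rs A [reading_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_readings <- function(rs, path) {
  out <- rs$readings[, c("subject_id", "timestamp", "value", "measure")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Time since enrollment, in study-period units
#'
#' The primary independent variable of all trend models: for each reading,
#' the elapsed time since the subject's enrollment anchor divided by
#' `scale_days`.  With the default `scale_days = 182.5` one unit equals the
#' nominal six-month study, so a slope coefficient reads directly as the
#' change in mmHg over the study period.
#'
#' @param rs A [reading_set()].
#' @param scale_days Positive number of days per time unit.
#' @return Numeric vector aligned with `rs$readings` rows.
#' @export
time_since_enrollment <- function(rs, scale_days = 182.5) {
  if (!is.numeric(scale_days) || scale_days <= 0) {
    stop_config("scale_days must be a positive number")
  }
  anchor <- rs$enrollment$enrollment_time[
    match(rs$readings$subject_id, rs$enrollment$subject_id)]
  days_between(rs$readings$timestamp, anchor) / scale_days
}

#' Hour of day of each reading
#'
#' Local-clock hour, truncated: a reading at 08:59 falls in hour 8.  Used as
#' the 24-level time-of-day covariate.
#'
#' @param x A [reading_set()] or a `POSIXct` vector.
#' @return Integer vector of hours in `0:23`.
#' @export
hour_of_day <- function(x) {
  ts <- if (inherits(x, "reading_set")) x$readings$timestamp else x
  as.POSIXlt(ts)$hour
}
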