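# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Elapsed time in days between two POSIXct vectors.
days_between <- function(t1, t0) {
  as.numeric(difftime(t1, t0, units = "days"))
}

# Parse character timestamps at minute (or finer) resolution, ISO 8601 first.
# Returns POSIXct with NA where parsing failed; callers decide how to react.
parse_timestamps <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) return(x)
  formats <- c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
    "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
    "%Y/%m/%d %H:%M:%OS", "%Y/%m/%d %H:%M",
    "%Y-%m-%d"
  )
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  pending <- !is.na(x)
  for (fmt in formats) {
    if (!any(pending)) break
    parsed <- as.POSIXct(x[pending], format = fmt, tz = tz)
    ok <- !is.na(parsed)
    out[which(pending)[ok]] <- parsed[ok]
    pending[pending] <- !ok
  }
  out
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("bptrend_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("bptrend_data_error", "error")))
}
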