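#' Residual covariance families for within-subject dependence
#'
#' A `cov_model` bundles a residual covariance family with its variance
#' parameters.  Three families are supported, all paired with a random
#' subject intercept of variance `sigma2_u`:
#'
#' * `"CS"` — compound symmetry: independent residuals, so all exchangeable
#'   within-subject correlation comes from the shared intercept.
#' * `"AR1"` — first-order autoregressive by measurement *order*:
#'   `cor(e_i, e_j) = rho^|i-j|` regardless of the actual lag.
#' * `"SP"` — spatial power law, the continuous-time generalisation:
#'   `cor(e_i, e_j) = rho^(|t_i - t_j| / lag_unit_days)`, which reduces to
#'   AR(1) when readings are equally spaced at one lag unit.
#'
#' @param kind One of `"CS"`, `"AR1"`, `"SP"`.
#' @param sigma2_u Random-intercept variance, mmHg^2 (>= 0).
#' @param sigma2 Residual variance, mmHg^2 (> 0).
#' @param rho Correlation parameter: in (-1, 1) for AR1, in (0, 1) for SP
#'   (fractional powers of a negative base are undefined); unused for CS.
#' @param lag_unit_days Lag unit for the SP exponent, days.  Default 1, so
#'   `rho` is the residual correlation at a one-day lag.
#' @return An object of class `cov_model`.
#' @export
cov_model <- function(kind = c("CS", "AR1", "SP"),
                      sigma2_u, sigma2, rho = NULL, lag_unit_days = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma2_u) || sigma2_u < 0) stop_config("sigma2_u must be >= 0")
  if (!is.numeric(sigma2) || sigma2 <= 0) stop_config("sigma2 must be > 0")
  if (kind == "CS") {
    rho <- NULL
  } else {
    if (is.null(rho)) stop_config(kind, " requires rho")
    if (kind == "AR1" && abs(rho) >= 1) stop_config("AR1 requires rho in (-1, 1)")
    if (kind == "SP" && (rho <= 0 || rho >= 1)) stop_config("SP requires rho in (0, 1)")
  }
  if (lag_unit_days <= 0) stop_config("lag_unit_days must be positive")
  structure(list(kind = kind, sigma2_u = sigma2_u, sigma2 = sigma2,
                 rho = rho, lag_unit_days = lag_unit_days),
            class = "cov_model")
}

#' @export
print.cov_model <- function(x, ...) {
  cat(sprintf("Covariance model %s: sigma2_u = %.4g, sigma2 = %.4g",
              x$kind, x$sigma2_u, x$sigma2))
  if (!is.null(x$rho)) {
    cat(sprintf(", rho = %.4g", x$rho))
    if (x$kind == "SP") cat(sprintf(" per %g day(s)", x$lag_unit_days))
  }
  cat("\n")
  invisible(x)
}

n_cov_params <- function(cm) if (cm$kind == "CS") 2L else 3L

#' Residual covariance block under compound symmetry
#'
#' Under CS the residuals themselves are independent, `Sigma_R = sigma2 * I`;
#' the exchangeable within-subject correlation enters through the random
#' intercept, giving the implied marginal block
#' `Sigma = sigma2_u * J + sigma2 * I`.
#'
#' @param cm A `"CS"` [cov_model()].
#' @param n Block size (number of readings for the subject).
#' @return The `n x n` residual covariance matrix `Sigma_R`.
#' @export
sigma_cs <- function(cm, n) {
  stopifnot(cm$kind == "CS")
  diag(cm$sigma2, n)
}

#' Residual covariance block under first-order autoregression
#'
#' Entries are `sigma2 * rho^|i-j|` by measurement order within the subject,
#' ignoring the actual elapsed time between readings.
#'
#' @param cm An `"AR1"` [cov_model()].
#' @param n Block size; rows must be time-ordered.
#' @return The `n x n` residual covariance matrix.
#' @export
sigma_ar1 <- function(cm, n) {
  stopifnot(cm$kind == "AR1")
  idx <- seq_len(n)
  cm$sigma2 * cm$rho^abs(outer(idx, idx, "-"))
}

#' Residual covariance block under the spatial power law
#'
#' Entries are `sigma2 * rho^(|t_i - t_j| / lag_unit_days)`.  Two readings
#' minutes apart have correlation near one, which makes the block nearly
#' singular — the motivation for [merge_close_readings()].
#'
#' @param cm An `"SP"` [cov_model()].
#' @param times Numeric vector of measurement times in days (any origin).
#' @return The `length(times)` square residual covariance matrix.
#' @export
sigma_sp <- function(cm, times) {
  stopifnot(cm$kind == "SP")
  lag <- abs(outer(times, times, "-")) / cm$lag_unit_days
  cm$sigma2 * cm$rho^lag
}

# Residual covariance block for any family; `times` in days.
sigma_r_block <- function(cm, times) {
  switch(cm$kind,
         CS = sigma_cs(cm, length(times)),
         AR1 = sigma_ar1(cm, length(times)),
         SP = sigma_sp(cm, times))
}

# Marginal within-subject block V_i = sigma2_u * J + Sigma_R.
v_block <- function(cm, times) {
  sigma_r_block(cm, times) + cm$sigma2_u
}

#' Diagnose near-singular residual correlation blocks
#'
#' Computes, per subject block, the reciprocal condition number of the
#' spatial power-law residual correlation matrix, and flags blocks below
#' `tol`.  For every flagged block the offending consecutive reading pairs
#' are listed: a pair is reported when its correlation exceeds
#' `1 - sqrt(tol)`, i.e. when its own 2x2 submatrix is within a square-root
#' margin of exact singularity.  (The looser pair criterion is deliberate:
#' a block can cross the `tol` threshold through the joint effect of pairs
#' that are individually just above it.)  Such pairs are exactly what
#' [merge_close_readings()] removes.
#'
#' @param x A [reading_set()], or a numeric vector of times in days for a
#'   single block.
#' @param cm An `"SP"` [cov_model()] supplying `rho` and the lag unit; the
#'   default probes at `rho = 0.2`/day, the magnitude typical of fitted
#'   day-scale residual correlation in home monitoring series.
#' @param tol Reciprocal-condition-number threshold.
#' @return An object of class `singularity_report`: a data frame of flagged
#'   blocks (`subject_id`, `measure`, `n`, `rcond`) with attribute `"pairs"`
#'   holding the offending timestamp pairs and their lags in hours.
#' @export
check_singularity <- function(x, cm = cov_model("SP", sigma2_u = 0, sigma2 = 1, rho = 0.2),
                              tol = 1e-3) {
  stopifnot(cm$kind == "SP")
  blocks <- if (inherits(x, "reading_set")) {
    r <- x$readings
    key <- paste(r$subject_id, r$measure, sep = "\r")
    idx <- split(seq_len(nrow(r)), factor(key, levels = unique(key)))
    lapply(idx, function(i) list(
      subject_id = r$subject_id[i[1L]],
      measure = r$measure[i[1L]],
      times = days_between(r$timestamp[i], r$timestamp[i[1L]]),
      stamps = r$timestamp[i]))
  } else {
    list(list(subject_id = "block", measure = "unspecified",
              times = as.numeric(x), stamps = NULL))
  }

  flagged <- list()
  pairs <- list()
  corr_crit <- 1 - sqrt(tol)
  for (b in blocks) {
    n <- length(b$times)
    if (n < 2L) next
    C <- cm$rho^(abs(outer(b$times, b$times, "-")) / cm$lag_unit_days)
    rc <- rcond(C)
    if (rc < tol) {
      flagged[[length(flagged) + 1L]] <- data.frame(
        subject_id = b$subject_id, measure = b$measure,
        n = n, rcond = rc, stringsAsFactors = FALSE)
      lag <- diff(b$times)
      bad <- which(cm$rho^(lag / cm$lag_unit_days) > corr_crit)
      if (length(bad)) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          subject_id = b$subject_id, measure = b$measure,
          index_first = bad, lag_hours = lag[bad] * 24,
          time_first = if (is.null(b$stamps)) b$times[bad] else b$stamps[bad],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(subject_id = character(0), measure = character(0),
               n = integer(0), rcond = numeric(0))
  rownames(out) <- NULL
  attr(out, "pairs") <- if (length(pairs)) do.call(rbind, pairs) else NULL
  attr(out, "tol") <- tol
  class(out) <- c("singularity_report", "data.frame")
  out
}

#' @export
print.singularity_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("No near-singular residual correlation blocks detected.\n")
  } else {
    cat(sprintf("%d block(s) with reciprocal condition number < %g:\n",
                nrow(x), attr(x, "tol")))
    print.data.frame(x)
    p <- attr(x, "pairs")
    if (!is.null(p)) {
      cat(sprintf("%d offending short-lag pair(s); consider merge_close_readings().\n",
                  nrow(p)))
    }
  }
  invisible(x)
}
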