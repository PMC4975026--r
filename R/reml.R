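#' Minus twice the restricted log-likelihood, block-diagonally
#'
#' For the mixed model `Y = X beta + Z u + e` with marginal covariance
#' `V = Z G Z' + R`, both `R` and `V` are block diagonal by subject, so the
#' restricted likelihood decomposes over subjects and dense `V` is never
#' materialised.  The value returned is
#'
#'   `log|V| + log|X' V^-1 X| + r' V^-1 r + (n - p) log(2 pi)`
#'
#' with `r` the generalised-least-squares residual at the profiled
#' `beta = (X' V^-1 X)^-1 X' V^-1 Y`.
#'
#' @param dm A [build_design()] object.
#' @param cm A [cov_model()] supplying the variance parameters.
#' @return The scalar `-2 l_R`, with attributes `"beta"` (profiled GLS fixed
#'   effects) and `"cov_beta"` (their covariance `(X' V^-1 X)^-1`).
#' @export
neg2_reml <- function(dm, cm) {
  p <- dm$p
  XtViX <- matrix(0, p, p)
  XtViY <- numeric(p)
  YtViY <- 0
  logdetV <- 0
  for (si in seq_along(dm$blocks)) {
    i <- dm$blocks[[si]]
    Vb <- v_block(cm, dm$times[i])
    L <- tryCatch(chol(Vb), error = function(e) NULL)
    if (is.null(L)) {
      stop_data("covariance block numerically singular for subject ",
                levels(dm$subject)[si],
                " (near-duplicate timestamps? run merge_close_readings)")
    }
    logdetV <- logdetV + 2 * sum(log(diag(L)))
    Wx <- backsolve(L, dm$X[i, , drop = FALSE], transpose = TRUE)
    wy <- backsolve(L, dm$Y[i], transpose = TRUE)
    XtViX <- XtViX + crossprod(Wx)
    XtViY <- XtViY + crossprod(Wx, wy)[, 1L]
    YtViY <- YtViY + sum(wy * wy)
  }
  R2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(R2)) stop_data("X' V^-1 X singular; design is rank deficient")
  beta <- backsolve(R2, backsolve(R2, XtViY, transpose = TRUE))
  quad <- YtViY - sum(beta * XtViY)
  val <- logdetV + 2 * sum(log(diag(R2))) + quad + (dm$n - p) * log(2 * pi)
  attr(val, "beta") <- stats::setNames(beta, colnames(dm$X))
  attr(val, "cov_beta") <- chol2inv(R2)
  val
}

# Moment-based starting variances: OLS residual variance split between the
# between-subject spread of residual means and the leftover.
start_variances <- function(dm) {
  bhat <- tryCatch(qr.coef(qr(dm$X), dm$Y), error = function(e) NULL)
  res <- if (is.null(bhat)) dm$Y - mean(dm$Y) else dm$Y - dm$X %*% ifelse(is.na(bhat), 0, bhat)
  sub_means <- vapply(dm$blocks, function(i) mean(res[i]), 0)
  s2u <- max(stats::var(sub_means), 1e-4)
  s2 <- max(stats::var(as.numeric(res)) - s2u, 1e-4)
  c(s2u = s2u, s2 = s2)
}

#' Fit the repeated-measures mixed model by REML
#'
#' Fits `Y = X beta + Z u + e` with random subject intercepts and the
#' chosen residual covariance family, by numerically minimising
#' [neg2_reml()] over the variance parameters (log variances; `rho` on a
#' tanh scale for AR1 and a logistic scale for SP) with the fixed effects
#' profiled out by generalised least squares at every step.  For the
#' correlation families the optimiser is restarted from several `rho`
#' values and the best optimum kept, making the fit deterministic given
#' the data and options.
#'
#' Inference on the time trend is Wald-normal: the reported 95% interval is
#' `estimate +/- 1.96 SE` and the p-value refers `estimate / SE` to the
#' standard normal.  `AIC = -2 l_R + 2 q` and `BIC = -2 l_R + q log(m)`
#' where `q` counts covariance parameters (2 for CS, 3 for AR1/SP) and `m`
#' is the number of subjects.
#'
#' @param rs A [reading_set()] (merge it first for SP; see Details).
#' @param kind Covariance family, `"CS"`, `"AR1"` or `"SP"`.
#' @param measure Optional measure label to subset on.
#' @param scale_days Days per unit of the time covariate.
#' @param lag_unit_days SP lag unit, days.
#' @param force Fit SP even when [check_singularity()] flags near-singular
#'   blocks (default `FALSE`: refuse with an error naming the remedy).
#' @param control List of optimiser settings: `rho_starts` (default
#'   `c(0.1, 0.3, 0.6)`), `reltol` (default `1e-10`), `maxit` (default 500).
#'
#' @details For `"SP"` on unmerged data, near-duplicate timestamps make a
#'   subject's covariance block numerically singular; unless `force = TRUE`
#'   the fit refuses such data and points to [merge_close_readings()].
#'
#' @return An object of class `mixed_fit`.
#' @export
fit_mixed <- function(rs, kind = c("SP", "AR1", "CS"), measure = NULL,
                      scale_days = 182.5, lag_unit_days = 1,
                      force = FALSE, control = list()) {
  kind <- match.arg(kind)
  dm <- build_design(rs, scale_days = scale_days, measure = measure)

  if (kind == "SP" && !force) {
    sing <- check_singularity(if (is.null(measure)) rs else
      subset_readings(rs, measure = measure))
    if (nrow(sing)) {
      stop_data("spatial power-law fit refused: ", nrow(sing),
                " subject block(s) have a near-singular residual correlation ",
                "matrix (short-lag readings). Run merge_close_readings() ",
                "first, or use force = TRUE.")
    }
  }
  fit_mixed_design(dm, kind = kind, lag_unit_days = lag_unit_days,
                   control = control)
}

# Profiled restricted likelihood: with V = sigma2 * W(lambda, rho),
# lambda = sigma2_u / sigma2, the optimal sigma2 has the closed form
# quad_W / (n - p), leaving a 1- or 2-parameter search surface.
# Per-block lag matrices are computed once and reused across evaluations.
reml_profiled <- function(dm, lagmats, lambda, rho, kind) {
  p <- dm$p
  WtX <- matrix(0, p, p)
  WtY <- numeric(p)
  YtY <- 0
  logdetW <- 0
  for (si in seq_along(dm$blocks)) {
    i <- dm$blocks[[si]]
    Wb <- switch(kind,
                 CS = diag(length(i)) + lambda,
                 rho^lagmats[[si]] + lambda)
    L <- tryCatch(chol(Wb), error = function(e) NULL)
    if (is.null(L)) return(list(value = 1e12))
    logdetW <- logdetW + 2 * sum(log(diag(L)))
    Wx <- backsolve(L, dm$X[i, , drop = FALSE], transpose = TRUE)
    wy <- backsolve(L, dm$Y[i], transpose = TRUE)
    WtX <- WtX + crossprod(Wx)
    WtY <- WtY + crossprod(Wx, wy)[, 1L]
    YtY <- YtY + sum(wy * wy)
  }
  R2 <- tryCatch(chol(WtX), error = function(e) NULL)
  if (is.null(R2)) return(list(value = 1e12))
  beta <- backsolve(R2, backsolve(R2, WtY, transpose = TRUE))
  quad <- YtY - sum(beta * WtY)
  np <- dm$n - p
  if (quad <= 0 || np <= 0) return(list(value = 1e12))
  s2 <- quad / np
  val <- np * log(s2) + logdetW + 2 * sum(log(diag(R2))) + np * (1 + log(2 * pi))
  list(value = val, sigma2 = s2)
}

# Core fitter on prepared design matrices (also used per subject by the
# sequential N-of-1 engine, with random intercepts switched off).
fit_mixed_design <- function(dm, kind, lag_unit_days = 1, control = list(),
                             with_random_intercept = TRUE) {
  rho_starts <- control$rho_starts %||% c(0.1, 0.3, 0.6)
  reltol <- control$reltol %||% 1e-10
  maxit <- control$maxit %||% 500L
  if (dm$n <= dm$p) {
    stop_data("too few observations (", dm$n, ") for ", dm$p,
              " fixed-effect columns")
  }

  lagmats <- if (kind == "CS") NULL else lapply(dm$blocks, function(i) {
    if (kind == "AR1") {
      idx <- seq_along(i)
      abs(outer(idx, idx, "-"))
    } else {
      abs(outer(dm$times[i], dm$times[i], "-")) / lag_unit_days
    }
  })
  rho_link <- if (kind == "AR1") atanh else stats::qlogis
  rho_inv <- if (kind == "AR1") tanh else stats::plogis

  objective <- function(theta) {
    lambda <- if (with_random_intercept) exp(theta[1L]) else 0
    rho <- if (kind == "CS") 0 else rho_inv(theta[length(theta)])
    reml_profiled(dm, lagmats, lambda, rho, kind)$value
  }

  sv <- start_variances(dm)
  lambda_start <- log(max(sv[["s2u"]] / sv[["s2"]], 1e-3))
  n_par <- as.integer(with_random_intercept) + as.integer(kind != "CS")
  starts <- if (kind == "CS") list(lambda_start) else
    lapply(rho_starts, function(r) {
      if (with_random_intercept) c(lambda_start, rho_link(r)) else rho_link(r)
    })

  best <- NULL
  for (s in starts) {
    opt <- if (n_par == 1L) {
      o <- stats::optim(s, objective, method = "Brent",
                        lower = -15, upper = 15,
                        control = list(maxit = maxit))
      o
    } else {
      stats::optim(s, objective, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  lambda_hat <- if (with_random_intercept) exp(best$par[1L]) else 0
  rho_hat <- if (kind == "CS") NULL else rho_inv(best$par[length(best$par)])
  s2_hat <- reml_profiled(dm, lagmats, lambda_hat, rho_hat %||% 0, kind)$sigma2
  cm <- cov_model(kind, sigma2_u = lambda_hat * s2_hat, sigma2 = s2_hat,
                  rho = rho_hat, lag_unit_days = lag_unit_days)
  val <- neg2_reml(dm, cm)
  beta <- attr(val, "beta")
  se <- sqrt(diag(attr(val, "cov_beta")))
  names(se) <- names(beta)

  est <- beta[["time"]]
  se_t <- se[["time"]]
  z <- est / se_t
  q <- if (kind == "CS") 2L else 3L
  if (!with_random_intercept) q <- q - 1L
  m <- length(dm$blocks)

  structure(
    list(kind = kind,
         beta = data.frame(term = names(beta), estimate = as.numeric(beta),
                           se = as.numeric(se), stringsAsFactors = FALSE),
         beta_time = list(estimate = est, se = se_t,
                          ci_lower = est - 1.96 * se_t,
                          ci_upper = est + 1.96 * se_t,
                          p_value = 2 * stats::pnorm(-abs(z))),
         cov = cm,
         neg2_reml = as.numeric(val),
         aic = as.numeric(val) + 2 * q,
         bic = as.numeric(val) + q * log(m),
         q = q,
         converged = best$convergence == 0L,
         n_obs = dm$n, n_subjects = m,
         scale_days = dm$scale_days,
         measure = dm$measure %||% "unspecified",
         response_checksum = sum(dm$Y)),
    class = "mixed_fit"
  )
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("Mixed model (REML), residual covariance %s\n", x$kind))
  cat(sprintf("  %d observations on %d subjects (%s)\n",
              x$n_obs, x$n_subjects, x$measure))
  bt <- x$beta_time
  cat(sprintf("  time trend: %.3f mmHg per study period (95%% CI %.3f, %.3f), p = %.3g\n",
              bt$estimate, bt$ci_lower, bt$ci_upper, bt$p_value))
  cat(sprintf("  sigma2_u = %.3f, sigma2 = %.3f", x$cov$sigma2_u, x$cov$sigma2))
  if (!is.null(x$cov$rho)) cat(sprintf(", rho = %.3f", x$cov$rho))
  cat(sprintf("\n  -2 logLik(REML) = %.2f, AIC = %.2f, BIC = %.2f\n",
              x$neg2_reml, x$aic, x$bic))
  if (!x$converged) cat("  WARNING: optimiser did not report convergence\n")
  invisible(x)
}

#' Rank fitted models by information criteria
#'
#' @param ... [fit_mixed()] objects (or a single list of them), all fitted
#'   to the same response vector.
#' @return A data frame sorted by AIC (ties broken by BIC, then by fewer
#'   covariance parameters), one row per fit.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "mixed_fit")) fits <- fits[[1L]]
  stopifnot(all(vapply(fits, inherits, TRUE, "mixed_fit")))
  cks <- vapply(fits, function(f) f$response_checksum, 0)
  ns <- vapply(fits, function(f) f$n_obs, 0)
  if (length(unique(ns)) > 1L || max(abs(cks - cks[1L])) > 1e-6 * max(1, abs(cks[1L]))) {
    stop_config("compare_models requires fits to the same response vector")
  }
  tab <- data.frame(
    model = vapply(fits, function(f) f$kind, ""),
    q = vapply(fits, function(f) f$q, 0L),
    neg2_reml = vapply(fits, function(f) f$neg2_reml, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    bic = vapply(fits, function(f) f$bic, 0),
    beta_time = vapply(fits, function(f) f$beta_time$estimate, 0),
    ci_lower = vapply(fits, function(f) f$beta_time$ci_lower, 0),
    ci_upper = vapply(fits, function(f) f$beta_time$ci_upper, 0),
    p_value = vapply(fits, function(f) f$beta_time$p_value, 0),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$aic, tab$bic, tab$q), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
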