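test_that("design matrix uses observed hour levels with the lowest as reference", {
  rs <- make_rs(c("A", "A", "B", "B"),
                c("2013-09-01T08:10", "2013-09-02T14:30",
                  "2013-09-01T08:40", "2013-09-03T14:05"),
                c(120, 118, 130, 131))
  dm <- build_design(rs)
  expect_equal(colnames(dm$X), c("(Intercept)", "time", "hour14"))
  expect_equal(dm$p, 3L)
  # all readings at one hour: the hour covariate drops entirely
  rs1 <- make_rs("A", c("2013-09-01T08:10", "2013-09-02T08:30", "2013-09-03T08:55"),
                 c(120, 119, 118))
  expect_equal(colnames(build_design(rs1)$X), c("(Intercept)", "time"))
  # generated data: 2 + (observed hours - 1) columns
  st <- small_cohort(seed = 9)
  dm2 <- build_design(st$rs)
  expect_equal(dm2$p, 2L + length(unique(hour_of_day(st$rs))) - 1L)
  expect_equal(qr(dm2$X)$rank, dm2$p)
})

test_that("block-diagonal restricted likelihood equals the dense oracle", {
  dm <- build_design(tiny_rs(n_subjects = 3, n_per = 8, seed = 5))
  expect_lte(dm$n, 30)
  cms <- list(
    cov_model("CS", sigma2_u = 120, sigma2 = 80),
    cov_model("CS", sigma2_u = 0, sigma2 = 50),
    cov_model("AR1", sigma2_u = 90, sigma2 = 60, rho = 0.4),
    cov_model("AR1", sigma2_u = 50, sigma2 = 70, rho = -0.3),
    cov_model("SP", sigma2_u = 100, sigma2 = 85, rho = 0.2),
    cov_model("SP", sigma2_u = 10, sigma2 = 40, rho = 0.8, lag_unit_days = 2)
  )
  for (cm in cms) {
    v <- neg2_reml(dm, cm)
    expect_equal(as.numeric(v), dense_neg2_reml(dm, cm), tolerance = 1e-8)
  }
})

test_that("the independence limit reduces to ordinary least squares REML", {
  dm <- build_design(tiny_rs(n_subjects = 3, n_per = 10, seed = 6))
  cm <- cov_model("CS", sigma2_u = 0, sigma2 = 64)
  v <- neg2_reml(dm, cm)
  # closed form with V = sigma2 * I
  fit <- lm.fit(dm$X, dm$Y)
  rss <- sum(fit$residuals^2)
  closed <- (dm$n - dm$p) * log(64) + determinant(crossprod(dm$X))$modulus +
    rss / 64 + (dm$n - dm$p) * log(2 * pi)
  expect_equal(as.numeric(v), as.numeric(closed), tolerance = 1e-10)
})

test_that("restricted likelihood is invariant to subject order and hour reference", {
  st <- small_cohort(n_subjects = 4, target_readings = 10, seed = 8)
  dm <- build_design(st$rs)
  cm <- cov_model("SP", sigma2_u = 80, sigma2 = 60, rho = 0.25)
  v <- neg2_reml(dm, cm)

  # permute subjects
  r <- st$rs$readings
  ids <- unique(r$subject_id)
  relabel <- stats::setNames(rev(sprintf("Z%02d", seq_along(ids))), ids)
  r2 <- r
  r2$subject_id <- unname(relabel[r$subject_id])
  enr2 <- st$rs$enrollment
  enr2$subject_id <- unname(relabel[enr2$subject_id])
  rs2 <- reading_set(r2, enrollment = enr2)
  expect_equal(as.numeric(neg2_reml(build_design(rs2), cm)), as.numeric(v),
               tolerance = 1e-10)

  # recode the hour indicators against the highest observed hour instead:
  # a unimodular linear reparameterisation, so the REML value is unchanged
  hrs <- sort(unique(hour_of_day(st$rs)))
  hr <- hour_of_day(st$rs)
  X2 <- cbind(1, dm$X[, "time"])
  for (h in hrs[-length(hrs)]) X2 <- cbind(X2, as.numeric(hr == h))
  dm2 <- dm
  dm2$X <- X2
  dm2$p <- ncol(X2)
  expect_equal(as.numeric(neg2_reml(dm2, cm)), as.numeric(v), tolerance = 1e-8)
})

test_that("with frozen variance parameters the fixed effects are the GLS solution", {
  st <- small_cohort(n_subjects = 4, target_readings = 10, seed = 10)
  dm <- build_design(st$rs)
  cm <- cov_model("AR1", sigma2_u = 100, sigma2 = 81, rho = 0.3)
  v <- neg2_reml(dm, cm)
  V <- matrix(0, dm$n, dm$n)
  for (i in dm$blocks) {
    k <- seq_along(i)
    V[i, i] <- 100 + 81 * 0.3^abs(outer(k, k, "-"))
  }
  Vi <- solve(V)
  beta_gls <- solve(t(dm$X) %*% Vi %*% dm$X, t(dm$X) %*% Vi %*% dm$Y)[, 1]
  expect_equal(unname(attr(v, "beta")), unname(beta_gls), tolerance = 1e-8)
})

test_that("SP and AR1 likelihood surfaces coincide on equally spaced data", {
  # daily readings at a fixed hour: lag = lag_unit everywhere
  days <- 0:19
  ts <- as.POSIXct("2013-09-01 08:00", tz = "UTC") + days * 86400
  set.seed(77)
  rs <- make_rs(rep(c("A", "B"), each = 20), rep(ts, 2),
                120 + rnorm(40, 0, 5))
  dm <- build_design(rs)
  for (rho in c(0.1, 0.35, 0.7)) {
    v_sp <- neg2_reml(dm, cov_model("SP", 25, 20, rho = rho))
    v_ar <- neg2_reml(dm, cov_model("AR1", 25, 20, rho = rho))
    expect_equal(as.numeric(v_sp), as.numeric(v_ar), tolerance = 1e-8)
  }
  f_sp <- fit_mixed(rs, "SP")
  f_ar <- fit_mixed(rs, "AR1")
  expect_equal(f_sp$neg2_reml, f_ar$neg2_reml, tolerance = 1e-6)
  expect_equal(f_sp$beta_time$estimate, f_ar$beta_time$estimate, tolerance = 1e-4)
})

test_that("fit_mixed recovers generating parameters and matches nlme", {
  st <- simulate_study(sim_config(n_subjects = 12, target_readings = 80,
                                  readings_sd = 10, seed = 21))
  mrs <- merge_close_readings(st$rs)$rs
  fit <- fit_mixed(mrs, kind = "SP")
  expect_true(fit$converged)
  # truth -2 lies inside the fit's own 95% interval
  expect_gt(-2, fit$beta_time$ci_lower)
  expect_lt(-2, fit$beta_time$ci_upper)

  # independent fit of the same model via nlme's continuous-time AR(1)
  library(nlme)
  r <- mrs$readings
  d <- data.frame(y = r$value, t = time_since_enrollment(mrs),
                  td = as.numeric(r$timestamp) / 86400,
                  hr = factor(hour_of_day(mrs)), id = r$subject_id)
  ctrl <- lmeControl(opt = "optim")
  lf <- lme(y ~ t + hr, random = ~ 1 | id, data = d,
            correlation = corCAR1(form = ~ td | id), method = "REML",
            control = ctrl)
  expect_equal(fit$beta_time$estimate, unname(fixef(lf)[["t"]]), tolerance = 1e-3)
  expect_equal(fit$beta_time$se, sqrt(vcov(lf)["t", "t"]), tolerance = 1e-3)
  expect_equal(fit$cov$rho,
               unname(coef(lf$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
  expect_equal(fit$cov$sigma2, lf$sigma^2, tolerance = 1e-2)
})

test_that("SP refuses unmerged short-lag data unless forced", {
  st <- small_cohort(n_subjects = 8, target_readings = 80, seed = 7)
  expect_error(fit_mixed(st$rs, kind = "SP"), "merge_close_readings",
               class = "bptrend_data_error")
  mrs <- merge_close_readings(st$rs)$rs
  expect_s3_class(fit_mixed(mrs, kind = "SP"), "mixed_fit")
})

test_that("model comparison ranks by AIC with documented tie-breaks", {
  st <- simulate_study(sim_config(n_subjects = 8, target_readings = 50,
                                  readings_sd = 5, seed = 31))
  mrs <- merge_close_readings(st$rs)$rs
  fits <- list(CS = fit_mixed(mrs, "CS"), AR1 = fit_mixed(mrs, "AR1"),
               SP = fit_mixed(mrs, "SP"))
  tab <- compare_models(fits)
  expect_equal(nrow(tab), 3L)
  expect_true(!is.unsorted(tab$aic))
  # AIC-BIC gap is q (log m - 2) by construction
  m <- fits$CS$n_subjects
  expect_equal(tab$bic - tab$aic, tab$q * (log(m) - 2), tolerance = 1e-10)
  # the data were generated with continuous-time decay: SP beats CS
  expect_lt(tab$aic[tab$model == "SP"], tab$aic[tab$model == "CS"])
  # refuse to rank fits on different responses
  other <- fit_mixed(merge_close_readings(small_cohort(seed = 32)$rs)$rs, "CS")
  expect_error(compare_models(fits$CS, other), class = "bptrend_config_error")
})
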