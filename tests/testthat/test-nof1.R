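test_that("a noiseless declining line is recovered exactly", {
  days <- seq(0, 180, by = 6)
  ts <- as.POSIXct("2013-09-01 08:00", tz = "UTC") + days * 86400
  rs <- make_rs("A", ts, 120 - 2 * days / 182.5)
  f <- suppressWarnings(fit_subject(rs))  # lm warns on an essentially perfect fit
  expect_equal(f$slope, -2, tolerance = 1e-10)
  expect_equal(f$direction, "decrease")
  expect_lt(f$p_value, 1e-12)
})

test_that("a flat series has slope zero", {
  days <- seq(0, 100, by = 10)
  ts <- as.POSIXct("2013-09-01 08:00", tz = "UTC") + days * 86400
  f <- suppressWarnings(fit_subject(make_rs("A", ts, rep(120, length(days)))))
  expect_equal(f$slope, 0, tolerance = 1e-12)
  expect_equal(f$direction, "zero")
})

test_that("too few readings or times is an error; aliased hours fall back", {
  ts2 <- as.POSIXct("2013-09-01 08:00", tz = "UTC") + c(0, 1) * 86400
  expect_error(fit_subject(make_rs("A", ts2, c(120, 121))),
               class = "bptrend_data_error")
  # hour perfectly collinear with time: hour term dropped with a warning
  ts3 <- as.POSIXct("2013-09-01 00:00", tz = "UTC") +
    c(8, 32, 56) * 3600  # 08:00 day 0, 08:00 day 1... shifted to distinct hours
  rs3 <- make_rs("A", as.POSIXct("2013-09-01 00:00", tz = "UTC") +
                   c(8 * 3600, 86400 + 9 * 3600, 2 * 86400 + 8 * 3600 + 60),
                 c(120, 119, 118))
  f3 <- suppressWarnings(fit_subject(rs3))
  expect_s3_class(f3, "subject_fit")
})

test_that("noisy subject-level slopes are estimated without systematic bias", {
  # one subject, slope -2 over the study period, autocorrelation-free noise
  hits <- 0L
  n_sim <- 500L
  for (s in seq_len(n_sim)) {
    set.seed(9000 + s)
    days <- sort(runif(160, 0, 183))
    ts <- as.POSIXct("2013-09-01 06:00", tz = "UTC") + days * 86400
    rs <- make_rs("A", ts, 120 - 2 * days / 182.5 + rnorm(160, 0, 8))
    f <- fit_subject(rs)
    if (abs(f$slope - (-2)) <= 2 * f$slope_se) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.93)
})

test_that("exact sign test matches brute-force enumeration and binom.test", {
  for (a in 0:12) {
    for (b in 0:12) {
      if (a + b == 0) next
      p <- sign_test_exact(a, b)
      expect_equal(p, brute_force_sign_p(a, b), tolerance = 1e-12)
      expect_equal(p, stats::binom.test(a, a + b)$p.value, tolerance = 1e-12)
      expect_equal(p, sign_test_exact(b, a), tolerance = 1e-12)  # symmetry
    }
  }
  expect_equal(sign_test_exact(9, 9), 1)
  expect_error(sign_test_exact(0, 0), class = "bptrend_data_error")
})

test_that("slope aggregation: weightings, symmetry, and mean reduction", {
  fits <- data.frame(
    subject_id = c("A", "B"), n_readings = c(50, 50),
    slope = c(-1, 1), slope_se = c(0.5, 0.5),
    p_value = c(0.1, 0.1), direction = c("decrease", "increase"),
    stringsAsFactors = FALSE
  )
  s <- summarize_slopes(fits, n_boot = 200, seed = 3)
  expect_equal(s$mean_slope, 0)
  expect_equal(s$weighted_mean_slope, 0)
  expect_equal(s$ivw_mean_slope, 0)
  expect_equal(s$n_decrease, 1L)
  expect_equal(s$n_increase, 1L)
  expect_equal(s$sign_test_p, 1)

  # unequal weights: verify the sqrt(n) mean against the direct formula
  fits2 <- data.frame(
    subject_id = c("A", "B", "C"), n_readings = c(100, 25, 400),
    slope = c(-3, 1, 2), slope_se = c(0.4, 1.2, 0.2),
    p_value = 0.1, direction = c("decrease", "increase", "increase"),
    stringsAsFactors = FALSE
  )
  s2 <- summarize_slopes(fits2, n_boot = 200, seed = 3)
  w <- sqrt(fits2$n_readings)
  expect_equal(s2$weighted_mean_slope, sum(w * fits2$slope) / sum(w))
  iv <- 1 / fits2$slope_se^2
  expect_equal(s2$ivw_mean_slope, sum(iv * fits2$slope) / sum(iv))
  # with identical weights every weighting reduces to the arithmetic mean
  fits3 <- fits2
  fits3$n_readings <- 64
  fits3$slope_se <- 0.7
  s3 <- summarize_slopes(fits3, n_boot = 100, seed = 1)
  expect_equal(s3$weighted_mean_slope, s3$mean_slope, tolerance = 1e-12)
  expect_equal(s3$ivw_mean_slope, s3$mean_slope, tolerance = 1e-12)
})

test_that("bootstrap interval is reproducible, order-invariant, and covers the estimate", {
  st <- small_cohort(n_subjects = 10, target_readings = 50, seed = 12)
  fits <- nof1_fits(st$rs)
  s1 <- summarize_slopes(fits, n_boot = 2000, seed = 99)
  s2 <- summarize_slopes(fits, n_boot = 2000, seed = 99)
  expect_identical(s1$bootstrap_ci, s2$bootstrap_ci)
  shuffled <- fits[rev(seq_len(nrow(fits))), ]
  s3 <- summarize_slopes(shuffled, n_boot = 2000, seed = 99)
  expect_identical(s1$bootstrap_ci, s3$bootstrap_ci)
  expect_lte(s1$bootstrap_ci[1], s1$point_estimate)
  expect_gte(s1$bootstrap_ci[2], s1$point_estimate)
  s4 <- summarize_slopes(fits, n_boot = 2000, seed = 100)
  expect_false(identical(s1$bootstrap_ci, s4$bootstrap_ci))
})

test_that("cohort-level N-of-1 run detects a shared declining trend", {
  st <- simulate_study(sim_config(n_subjects = 15, target_readings = 120,
                                  readings_sd = 20, beta_time = -6, seed = 14))
  fits <- nof1_fits(st$rs)
  expect_equal(nrow(fits), 15L)
  s <- summarize_slopes(fits, n_boot = 2000, seed = 1)
  expect_gt(s$n_decrease, s$n_increase)
  expect_lt(s$weighted_mean_slope, 0)
})
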