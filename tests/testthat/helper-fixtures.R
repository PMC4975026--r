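# Small fixture builders shared across test files.

# A reading_set built directly from vectors of ISO timestamps.
make_rs <- function(subject, timestamp, value, measure = "systolic",
                    enrollment = NULL) {
  suppressWarnings(reading_set(
    data.frame(subject_id = subject, timestamp = timestamp, value = value,
               measure = measure, stringsAsFactors = FALSE),
    enrollment = enrollment
  ))
}

# Write a reading_set (or raw data frame) to a temp CSV and return its path.
write_tmp_csv <- function(df, ...) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A small synthetic cohort that runs fast; conditions are the generator's
# defaults except for size.
small_cohort <- function(n_subjects = 6, target_readings = 40, seed = 11, ...) {
  simulate_study(sim_config(n_subjects = n_subjects,
                            target_readings = target_readings,
                            readings_sd = 5, seed = seed, ...))
}

# A tiny irregular reading set with subject-chosen times, built directly
# (no generator) so the instance size is exact.
tiny_rs <- function(n_subjects = 3, n_per = 8, seed = 5) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(i) {
    days <- sort(runif(n_per, 0, 60))
    hours <- sample(c(7, 8, 15, 16), n_per, replace = TRUE)
    data.frame(
      subject_id = sprintf("P%d", i),
      timestamp = as.POSIXct("2013-09-01", tz = "UTC") +
        (days + hours / 24) * 86400,
      value = 125 + rnorm(1, 0, 10) + rnorm(n_per, 0, 8),
      measure = "systolic", stringsAsFactors = FALSE
    )
  })
  reading_set(do.call(rbind, rows))
}

# Dense-matrix restricted likelihood by direct inversion: the independent
# oracle for the block-diagonal implementation.
dense_neg2_reml <- function(dm, cm) {
  n <- dm$n
  V <- matrix(0, n, n)
  for (i in dm$blocks) {
    t_i <- dm$times[i]
    Sr <- switch(cm$kind,
                 CS = diag(cm$sigma2, length(i)),
                 AR1 = cm$sigma2 * cm$rho^abs(outer(seq_along(i), seq_along(i), "-")),
                 SP = cm$sigma2 * cm$rho^(abs(outer(t_i, t_i, "-")) / cm$lag_unit_days))
    V[i, i] <- Sr + cm$sigma2_u
  }
  Vi <- solve(V)
  XtViX <- t(dm$X) %*% Vi %*% dm$X
  beta <- solve(XtViX, t(dm$X) %*% Vi %*% dm$Y)
  r <- dm$Y - dm$X %*% beta
  as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
               t(r) %*% Vi %*% r + (n - dm$p) * log(2 * pi))
}

# Brute-force two-sided exact binomial p (minlike), independent of the
# package's implementation: enumerate all outcomes.
brute_force_sign_p <- function(a, b) {
  n <- a + b
  p_obs <- choose(n, a) * 0.5^n
  total <- 0
  for (k in 0:n) {
    pk <- choose(n, k) * 0.5^n
    if (pk <= p_obs * (1 + 1e-7)) total <- total + pk
  }
  total
}
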