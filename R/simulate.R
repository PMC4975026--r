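#' Default hour-of-day effects for the generator
#'
#' A smooth diurnal profile of amplitude `amplitude` mmHg peaking at
#' `peak_hour` (early morning, matching home monitoring practice of a first
#' reading before daytime activity).
#'
#' @param amplitude Peak offset, mmHg.
#' @param peak_hour Hour (0-23) of the maximum.
#' @return Named numeric vector of length 24, hours `"0"`..`"23"`.
#' @export
default_hour_effects <- function(amplitude = 3, peak_hour = 7) {
  h <- 0:23
  stats::setNames(amplitude * cos(2 * pi * (h - peak_hour) / 24), h)
}

#' Configuration of a synthetic home-monitoring study
#'
#' Describes the study a generator run emulates: a cohort of hypertensive
#' subjects measuring blood pressure at self-chosen times (about three
#' active days a week, a morning and an afternoon session each), with
#' staggered enrollment, between-subject intercept variation, residual
#' autocorrelation decaying in continuous time, and occasional repeat
#' readings minutes apart.  All numbers are invented defaults chosen to
#' resemble a realistic six-month cohort; none are estimates from any real
#' dataset.
#'
#' @param n_subjects Number of subjects (default 38).
#' @param days Per-subject study length in days (default 183).
#' @param target_readings Mean readings per subject (default 165).
#' @param readings_sd Between-subject SD of the reading count (default 70).
#' @param beta_time True trend, mmHg per study period of 182.5 days
#'   (default -2).
#' @param beta0 Grand intercept, mmHg (default 130; use ~80 for a
#'   diastolic-like series).
#' @param hour_effects Named length-24 vector of mmHg offsets by hour.
#' @param sigma_u Between-subject intercept SD, mmHg (default 12).
#' @param sigma Residual SD, mmHg (default 9).
#' @param rho Residual autocorrelation at a one-day lag (default 0.2).
#' @param short_lag_pair_rate Probability that a session emits repeat
#'   readings minutes apart (default 0.09; repeat clusters have geometric
#'   size so most are pairs).
#' @param pair_cluster_p Geometric parameter of the repeat-cluster size;
#'   `pair_cluster_p` of clusters are simple pairs (default 0.61).
#' @param staggered_entry_days Enrollment dates spread uniformly over this
#'   many days (default 135, so calendar data span about 10.5 months).
#' @param measure Measure label stamped on the readings.
#' @param start_date Calendar date of the first possible enrollment.
#' @param seed Integer seed; one global seed drives per-subject substreams
#'   so adding a subject leaves the others unchanged.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 38L, days = 183, target_readings = 165,
                       readings_sd = 70, beta_time = -2, beta0 = 130,
                       hour_effects = default_hour_effects(),
                       sigma_u = 12, sigma = 9, rho = 0.2,
                       short_lag_pair_rate = 0.09, pair_cluster_p = 0.61,
                       staggered_entry_days = 135,
                       measure = "systolic",
                       start_date = "2013-08-15", seed = 1L) {
  stopifnot(n_subjects >= 1, days > 0, target_readings > 0,
            sigma_u >= 0, sigma >= 0, rho > 0, rho < 1,
            short_lag_pair_rate >= 0, short_lag_pair_rate <= 1,
            pair_cluster_p > 0, pair_cluster_p <= 1,
            staggered_entry_days >= 0, length(hour_effects) == 24L)
  structure(
    list(n_subjects = as.integer(n_subjects), days = days,
         target_readings = target_readings, readings_sd = readings_sd,
         beta_time = beta_time, beta0 = beta0, hour_effects = hour_effects,
         sigma_u = sigma_u, sigma = sigma, rho = rho,
         short_lag_pair_rate = short_lag_pair_rate,
         pair_cluster_p = pair_cluster_p,
         staggered_entry_days = staggered_entry_days,
         measure = measure, start_date = start_date,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Deterministic per-subject substream seeds below 2^31.
subject_seed <- function(seed, i, stream) {
  (as.numeric(seed) * 2654435761 + i * 40503 + stream * 69069) %% 2147483647
}

#' Simulate self-chosen measurement times
#'
#' Draws, per subject: a uniform enrollment offset; a per-subject target
#' reading count (normal, truncated below); active days at the rate that
#' meets the target (about 3 days/week at defaults); one morning-heavy and
#' one afternoon session per active day; and, with probability
#' `short_lag_pair_rate`, repeat readings 2-40 minutes after a session's
#' first reading.
#'
#' @param cfg A [sim_config()].
#' @return A list per subject with `enrollment` (`POSIXct`) and `times`
#'   (sorted `POSIXct` vector).
#' @export
simulate_sampling_times <- function(cfg) {
  start <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  morning_hours <- 5:11
  morning_w <- c(1, 2, 4, 4, 2, 1.5, 1)
  # afternoon sessions start at 13:00 so a session pair is always > 1 h apart
  afternoon_hours <- 13:22
  afternoon_w <- c(2, 3, 3, 3, 2.5, 2, 1.5, 1, 0.75, 0.5)
  mean_cluster_extra <- cfg$short_lag_pair_rate / cfg$pair_cluster_p

  out <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    set.seed(subject_seed(cfg$seed, i, 1L))
    # enrollment anchors at a date boundary so session hours are clock hours
    enroll_day <- floor(stats::runif(1, 0, cfg$staggered_entry_days + 1e-9))
    n_target <- max(20, stats::rnorm(1, cfg$target_readings, cfg$readings_sd))
    p_active <- min(1, n_target / (cfg$days * 2 * (1 + mean_cluster_extra)))
    active <- which(stats::runif(cfg$days) < p_active) - 1L

    times <- numeric(0)
    for (d in active) {
      for (sess in 1:2) {
        hour <- if (sess == 1) {
          sample(morning_hours, 1, prob = morning_w)
        } else {
          sample(afternoon_hours, 1, prob = afternoon_w)
        }
        t0 <- d + (hour + stats::runif(1, 0, 60) / 60) / 24
        times <- c(times, t0)
        if (stats::runif(1) < cfg$short_lag_pair_rate) {
          n_extra <- 1L + stats::rgeom(1, cfg$pair_cluster_p)
          tt <- t0
          for (e in seq_len(n_extra)) {
            tt <- tt + stats::runif(1, 2, 40) / (24 * 60)
            times <- c(times, tt)
          }
        }
      }
    }
    enrollment <- start + as.difftime(enroll_day, units = "days")
    ts <- enrollment + as.difftime(sort(times), units = "days")
    # minute resolution, as devices report
    ts <- as.POSIXct(floor(as.numeric(ts) / 60) * 60,
                     origin = "1970-01-01", tz = "UTC")
    out[[i]] <- list(subject_id = sprintf("S%02d", i),
                     enrollment = enrollment, times = unique(ts))
  }
  out
}

#' Simulate blood pressure values on given times
#'
#' Values follow the generating model
#' `value = beta0 + u_i + beta_time * t/182.5 + hour_effect + e`, with
#' `u_i ~ N(0, sigma_u^2)` and residuals drawn recursively so that their
#' exact covariance is the spatial power law:
#' `e_1 ~ N(0, sigma^2)`,
#' `e_j = rho^dt * e_{j-1} + N(0, sigma^2 (1 - rho^(2 dt)))` with `dt` the
#' lag in days.  This guarantees generator/fitter consistency: the sample
#' covariance of simulated blocks converges to [sigma_sp()].
#'
#' @param times Output of [simulate_sampling_times()].
#' @param cfg The same [sim_config()].
#' @return An object of class `simulated_study`: list with `rs` (a
#'   [reading_set()]), `truth` (the config) and `latent` (per-subject
#'   random intercepts).
#' @export
simulate_values <- function(times, cfg) {
  rows <- vector("list", length(times))
  u_all <- numeric(length(times))
  for (i in seq_along(times)) {
    tt <- times[[i]]$times
    nt <- length(tt)
    set.seed(subject_seed(cfg$seed, i, 2L))
    u <- stats::rnorm(1, 0, cfg$sigma_u)
    u_all[i] <- u
    e <- numeric(nt)
    if (nt > 0) {
      e[1L] <- stats::rnorm(1, 0, cfg$sigma)
      if (nt > 1L) {
        dt <- diff(as.numeric(tt)) / 86400
        ar <- cfg$rho^dt
        innov_sd <- cfg$sigma * sqrt(1 - ar^2)
        z <- stats::rnorm(nt - 1L)
        for (j in 2:nt) e[j] <- ar[j - 1L] * e[j - 1L] + innov_sd[j - 1L] * z[j - 1L]
      }
    }
    t_scaled <- days_between(tt, times[[i]]$enrollment) / 182.5
    hr <- hour_of_day(tt)
    value <- cfg$beta0 + u + cfg$beta_time * t_scaled +
      unname(cfg$hour_effects[as.character(hr)]) + e
    rows[[i]] <- data.frame(
      subject_id = times[[i]]$subject_id,
      timestamp = tt, value = value, measure = cfg$measure,
      stringsAsFactors = FALSE
    )
  }
  readings <- do.call(rbind, rows)
  enrollment <- data.frame(
    subject_id = vapply(times, `[[`, "", "subject_id"),
    enrollment_time = as.POSIXct(vapply(times, function(x) as.numeric(x$enrollment), 0),
                                 origin = "1970-01-01", tz = "UTC"),
    stringsAsFactors = FALSE
  )
  structure(
    list(rs = reading_set(readings, enrollment = enrollment),
         truth = cfg,
         latent = stats::setNames(u_all, enrollment$subject_id)),
    class = "simulated_study"
  )
}

#' Generate a complete synthetic monitoring study
#'
#' Convenience wrapper: [simulate_sampling_times()] then
#' [simulate_values()].  Regenerating with the same config reproduces the
#' readings exactly.
#'
#' @param cfg A [sim_config()]; defaults describe the standard synthetic
#'   cohort (38 subjects, ~165 readings each over six months).
#' @return A `simulated_study`; see [simulate_values()].
#' @export
simulate_study <- function(cfg = sim_config()) {
  simulate_values(simulate_sampling_times(cfg), cfg)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Synthetic monitoring study (ground truth known)\n")
  cat(sprintf("  beta_time = %g mmHg/period, sigma_u = %g, sigma = %g, rho = %g/day, seed = %d\n",
              x$truth$beta_time, x$truth$sigma_u, x$truth$sigma,
              x$truth$rho, x$truth$seed))
  print(x$rs)
  invisible(x)
}
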