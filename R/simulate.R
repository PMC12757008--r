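# Synthetic measurement-burst study generator: participants, burst calendars,
# latent bivariate VAR series, minute-level wearable streams, evening surveys
# and MAR missingness, all reproducible from explicit seeds.

local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed) || is.na(seed)) {
    stop("a seed is required for reproducible simulation")
  }
  withr::local_seed(as.integer(seed) %% .Machine$integer.max, .local_envir = env)
  invisible(seed)
}

#' Population composition settings
#'
#' Distributional settings for [simulate_population()].  The defaults emulate
#' a two-region adult cohort stratified towards active runners: 46.3% women,
#' 57.1% in the high-pollution region, 56.8% runners, 43% university educated,
#' SES split roughly 2.5/80/17.5 (below average / average / above average),
#' age 18-65 with mean 38.1 (SD 12.55), and a 9-63 exercise-identity score
#' whose distribution differs by activity status (runners high, inactive low).
#'
#' @param p_female,p_high_pollution,p_runner,p_university binomial
#'   probabilities for the respective categories.
#' @param ses_probs length-3 probability vector (below average, average,
#'   above average); must sum to 1.
#' @param age_mean,age_sd,age_range truncated-normal age distribution.
#' @param exid_runner,exid_inactive `c(mean, sd)` of the exercise-identity
#'   score by activity status, truncated to `exid_range`.
#' @param exid_range bounds of the exercise-identity scale (9 items, 1-7).
#' @param ensure_levels if `TRUE` (default), guarantee that every declared
#'   categorical level appears at least once (smallest datasets only), by
#'   deterministically reassigning the first persons; keeps the encoded
#'   design matrix full rank at small n.
#' @return list of validated settings.
#' @export
participant_config <- function(p_female = 0.463, p_high_pollution = 0.571,
                               p_runner = 0.568, p_university = 0.430,
                               ses_probs = c(0.0254, 0.7978, 0.1768),
                               age_mean = 38.09, age_sd = 12.55,
                               age_range = c(18, 65),
                               exid_runner = c(48, 8), exid_inactive = c(28, 9),
                               exid_range = c(9, 63),
                               ensure_levels = TRUE) {
  probs <- c(p_female, p_high_pollution, p_runner, p_university)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("category probabilities must lie in [0, 1]")
  }
  if (length(ses_probs) != 3 || any(ses_probs < 0) ||
      abs(sum(ses_probs) - 1) > 1e-8) {
    stop("ses_probs must be 3 non-negative probabilities summing to 1")
  }
  stopifnot(age_range[1] < age_range[2], age_sd > 0,
            exid_runner[2] > 0, exid_inactive[2] > 0)
  list(p_female = p_female, p_high_pollution = p_high_pollution,
       p_runner = p_runner, p_university = p_university,
       ses_probs = ses_probs, age_mean = age_mean, age_sd = age_sd,
       age_range = age_range, exid_runner = exid_runner,
       exid_inactive = exid_inactive, exid_range = exid_range,
       ensure_levels = isTRUE(ensure_levels))
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a participant population
#'
#' Draws `n` participants with person-level covariates (age, gender, region,
#' education, socioeconomic status), activity status and a baseline
#' exercise-identity score, from the settings in [participant_config()].
#'
#' @param n number of participants (>= 1).
#' @param config a [participant_config()].
#' @param seed integer seed; identical seed and config give identical output.
#' @return data frame with columns `person_id`, `age`, `gender`, `region`,
#'   `education`, `ses`, `runner`, `exid`.
#' @export
simulate_population <- function(n, config = participant_config(), seed = 1) {
  stopifnot(n >= 1)
  local_seed(seed)
  lv <- covariate_levels()
  gender <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  region <- ifelse(stats::runif(n) < config$p_high_pollution,
                   "high_pollution", "low_pollution")
  runner <- stats::runif(n) < config$p_runner
  education <- ifelse(stats::runif(n) < config$p_university,
                      "university", "non_university")
  ses <- lv$ses[1L + findInterval(stats::runif(n),
                                  cumsum(config$ses_probs)[1:2])]
  age <- rtruncnorm1(n, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  ex_mean <- ifelse(runner, config$exid_runner[1], config$exid_inactive[1])
  ex_sd <- ifelse(runner, config$exid_runner[2], config$exid_inactive[2])
  exid <- rtruncnorm1(n, ex_mean, ex_sd,
                      config$exid_range[1], config$exid_range[2])

  out <- data.frame(
    person_id = sprintf("p%04d", seq_len(n)),
    age = age, gender = gender, region = region,
    education = education, ses = ses, runner = runner, exid = exid,
    stringsAsFactors = FALSE
  )
  if (config$ensure_levels && n >= 2) {
    out <- force_levels(out)
  }
  out
}

# Deterministically reassign the first persons so every declared level of
# every categorical covariate is represented (design-rank guarantee at small n).
force_levels <- function(participants) {
  lv <- covariate_levels()
  slot <- 1L
  for (nm in names(lv)) {
    for (level in lv[[nm]]) {
      if (!any(participants[[nm]] == level)) {
        participants[[nm]][slot] <- level
        slot <- slot %% nrow(participants) + 1L
      }
    }
  }
  participants
}

#' Burst calendar
#'
#' Assigns each participant a study entry date (uniform over the recruitment
#' window) and lays out measurement bursts of `burst_length` consecutive days
#' starting at fixed offsets from entry (defaults: months 0, 4, 8 and 12).
#' Bursts never overlap and burst k+1 starts after burst k ends.
#'
#' @param participants participant table.
#' @param entry_start,entry_end recruitment window (continuous entry).
#' @param n_bursts number of bursts (uses the first `n_bursts` offsets).
#' @param burst_length days per burst (14 = two weeks).
#' @param burst_offsets day offsets of each burst start from study entry.
#' @param seed integer seed.
#' @return data frame with `person_id`, `burst`, `start` (Date), `length`.
#' @export
burst_calendar <- function(participants,
                           entry_start = "2019-04-19", entry_end = "2021-08-31",
                           n_bursts = 4, burst_length = 14,
                           burst_offsets = c(0, 122, 244, 365),
                           seed = 1) {
  stopifnot(n_bursts >= 1, n_bursts <= length(burst_offsets), burst_length >= 2)
  off <- burst_offsets[seq_len(n_bursts)]
  if (n_bursts > 1 && any(diff(off) <= burst_length)) {
    stop("burst offsets must be spaced more than burst_length days apart")
  }
  local_seed(seed)
  n <- nrow(participants)
  window <- seq(as.Date(entry_start), as.Date(entry_end), by = "day")
  entry <- window[sample.int(length(window), n, replace = TRUE)]
  data.frame(
    person_id = rep(participants$person_id, each = n_bursts),
    burst = rep(seq_len(n_bursts), n),
    start = rep(entry, each = n_bursts) + rep(off, n),
    length = as.integer(burst_length),
    stringsAsFactors = FALSE
  )
}

#' Default true parameter set
#'
#' A complete [bvb_params()] whose values describe a plausible regime for
#' daily life-satisfaction / physical-activity dynamics in an adult cohort:
#' moderate first-order autoregression in both series (0.394 and 0.316),
#' negligible cross-lagged effects, a small positive contemporaneous
#' disturbance correlation at average exercise identity (link intercept
#' 0.0872, i.e. rho of about 0.087) that increases with exercise identity
#' (link slope 0.0105 per SD), disturbance SDs 1.2342 (logit-LS) and 0.5855
#' (log-PA), random-intercept SDs 1.1847 and 0.387, weekend-peaked weekly
#' periodicity and summer-peaked seasonality in the means, and small age,
#' gender and trend effects.  Mean-model coefficients are on the original
#' covariate scale (per year of age, per day in study, per indicator).
#'
#' @param ... named overrides of any [bvb_params()] field.
#' @return a [bvb_params()] object (without random effects; those are drawn
#'   per person at simulation time unless supplied).
#' @export
true_parameters <- function(...) {
  nm <- covariate_names()
  delta_L <- stats::setNames(c(
    -0.4327, 0.0017, 0.0151, 0.0910, -0.0917,
    0.2556, 0.2017, 0.2202, 0.3623, 0.7257, 0.4406,
    -0.0556, -0.2274, -0.0112, -0.0034, 0.0825, 0.2484,
    0.1270, 0.0225, -0.0270, -0.0903, 0.0422,
    -0.0273, 0.4257, 0.5129
  ), c("intercept", "day_in_study", "age", "gender_male", "region_high",
       paste0("wd_", c("tue", "wed", "thu", "fri", "sat", "sun")),
       paste0("mon_", c("feb", "mar", "apr", "may", "jun", "jul",
                        "aug", "sep", "oct", "nov", "dec")),
       "edu_university", "ses_average", "ses_above"))[nm]
  delta_P <- stats::setNames(c(
    6.1004, -0.0019, 0.0069, 0.0840, -0.0183,
    0.0914, 0.0490, 0.0713, 0.0752, 0.1676, 0.0388,
    0.0474, 0.1074, 0.1086, 0.1346, 0.2298, 0.2086,
    0.1952, 0.1985, 0.0846, 0.0797, 0.0520,
    0.0051, -0.0091, 0.0155
  ), names(delta_L))[nm]
  args <- list(
    delta_L = delta_L, delta_P = delta_P,
    beta = matrix(c(0.394, 0.0011, -0.0013, 0.316), 2, 2),  # column-major
    sigma_L = 1.2342, sigma_P = 0.5855,
    tau_L = 1.1847, tau_P = 0.387,
    alpha0 = 0.0872, alpha1 = 0.0105
  )
  over <- list(...)
  for (k in names(over)) args[[k]] <- over[[k]]
  do.call(bvb_params, args)
}

#' Simulate the latent bivariate series
#'
#' Generates the transformed responses (L, P) for every person-burst-day under
#' the VAR(1) model.  The first day of each burst is drawn from the stationary
#' distribution centered at `mu + m` (bursts are separated by months, so the
#' day-level Markov chain is not propagated across the gap; bursts are linked
#' only through the person's random intercepts).  Subsequent days follow the
#' VAR recursion with contemporaneously correlated Gaussian disturbances whose
#' correlation is `tanh(alpha0 + alpha1 * exid_std)`.
#'
#' @param participants participant table.
#' @param calendar burst calendar from [burst_calendar()].
#' @param params a [bvb_params()]; if `params$m` is `NULL` random intercepts
#'   are drawn `N(0, tau^2)` per person.
#' @param seed integer seed.
#' @return list with `latent` (data frame `person_id`, `burst`, `day`, `date`,
#'   `L`, `P`), `m` (realized random effects) and `exid_std`.
#' @export
simulate_latent_series <- function(participants, calendar, params, seed = 1) {
  if (spectral_radius(params$beta) >= 1) {
    stop("transition matrix is not stationary (spectral radius >= 1); refusing to simulate")
  }
  local_seed(seed)
  grid <- calendar_grid(calendar)
  entry <- tapply(as.integer(grid$date), grid$person_id, min)
  enc <- encode_covariates(participants, grid, entry_dates = entry,
                           standardize = FALSE)
  mu <- cbind(enc$X %*% params$delta_L, enc$X %*% params$delta_P)

  persons <- unique(grid$person_id)
  np <- length(persons)
  m <- params$m
  if (is.null(m)) {
    m <- cbind(stats::rnorm(np, 0, params$tau_L),
               stats::rnorm(np, 0, params$tau_P))
  }
  rownames(m) <- persons
  exid_std <- enc$exid_std[match(persons, grid$person_id)]
  names(exid_std) <- persons
  rho <- moderated_correlation(params$alpha0, params$alpha1, exid_std)

  pidx <- match(grid$person_id, persons)
  nrow_g <- nrow(grid)
  Y <- matrix(NA_real_, nrow_g, 2)
  # per-person Cholesky factors of disturbance and stationary covariance
  chE <- vector("list", np); chS <- vector("list", np)
  for (i in seq_len(np)) {
    E <- disturbance_covariance(params$sigma_L, params$sigma_P, rho[i])
    chE[[i]] <- chol(E)
    chS[[i]] <- chol(stationary_covariance(params$beta, E))
  }
  Z <- matrix(stats::rnorm(2 * nrow_g), nrow_g, 2)
  B <- params$beta
  w_prev <- c(0, 0)
  for (r in seq_len(nrow_g)) {
    i <- pidx[r]
    if (grid$day[r] == 1L) {
      w <- as.vector(Z[r, ] %*% chS[[i]])
    } else {
      w <- as.vector(B %*% w_prev) + as.vector(Z[r, ] %*% chE[[i]])
    }
    Y[r, ] <- mu[r, ] + m[i, ] + w
    w_prev <- w
  }
  latent <- data.frame(person_id = grid$person_id, burst = grid$burst,
                       day = grid$day, date = grid$date,
                       L = Y[, 1], P = Y[, 2], stringsAsFactors = FALSE)
  list(latent = latent, m = m, exid_std = exid_std)
}

#' Measurement rendering settings
#'
#' Controls how latent daily values are realized as observable measurements:
#' the sleep block (excluded from wear time), the distribution of daily wear
#' minutes, the fraction of worn minutes eligible to receive steps (the rest
#' are zero-step minutes that still carry a heart-rate reading), the maximum
#' offset between the two life-satisfaction slider items, and an optional
#' heart-rate dropout probability for worn minutes.
#'
#' @param sleep_start_min,sleep_minutes sleep block (minutes from midnight).
#' @param wear_mean,wear_sd,wear_min daily worn wake minutes (truncated
#'   normal, also capped by the available wake minutes).
#' @param active_frac fraction of worn minutes eligible for steps.
#' @param item_offset_max largest integer offset between the two LS items.
#' @param hr_dropout probability a worn minute lacks a heart-rate reading.
#' @return list of validated settings.
#' @export
render_config <- function(sleep_start_min = 0, sleep_minutes = 480,
                          wear_mean = 840, wear_sd = 60, wear_min = 120,
                          active_frac = 0.6, item_offset_max = 5,
                          hr_dropout = 0) {
  stopifnot(sleep_minutes >= 0, sleep_minutes < 1440,
            wear_mean > 0, wear_sd >= 0, wear_min > 0,
            active_frac > 0, active_frac <= 1,
            item_offset_max >= 0, hr_dropout >= 0, hr_dropout < 1)
  list(sleep_start_min = sleep_start_min, sleep_minutes = sleep_minutes,
       wear_mean = wear_mean, wear_sd = wear_sd, wear_min = wear_min,
       active_frac = active_frac, item_offset_max = item_offset_max,
       hr_dropout = hr_dropout)
}

# Shared measurement realization: one row per person-day with the daily
# quantities every observable is built from.  Deterministic given the seed,
# regardless of whether a minute stream is rendered afterwards.
realize_measurements <- function(latent, config = render_config(), seed = 1) {
  local_seed(seed)
  n <- nrow(latent)
  ls_target <- pmin(pmax(inv_transform_ls(latent$L), 0), 100)
  pa_target <- pmax(inv_transform_pa(latent$P), 0)

  wake <- 1440 - config$sleep_minutes
  wear_minutes <- round(rtruncnorm1(n, config$wear_mean, max(config$wear_sd, 1e-9),
                                    config$wear_min, wake))
  wear_hours <- wear_minutes / 60
  steps_total <- round(pa_target * wear_hours)

  off <- sample.int(config$item_offset_max + 1L, n, replace = TRUE) - 1L
  off <- pmin(off, floor(pmin(ls_target, 100 - ls_target)))
  item1 <- round(ls_target + off)
  item2 <- round(ls_target - off)

  data.frame(person_id = latent$person_id, burst = latent$burst,
             day = latent$day, date = latent$date,
             wear_minutes = wear_minutes, steps_total = steps_total,
             ls_item1 = item1, ls_item2 = item2, stringsAsFactors = FALSE)
}

#' Missingness mechanism settings
#'
#' Declares a missing-at-random mechanism for the daily table.  Missingness
#' probabilities may depend only on always-observed quantities (weekday and
#' person covariates); the constructor accepts exactly the fields below, so a
#' mechanism referencing the to-be-masked response cannot be expressed
#' (attempting to pass any other argument is an error).  Rates are
#' probabilities; weekend effects are added on Saturdays and Sundays and the
#' result is clipped to \[0, 1\].
#'
#' @param ls_rate,pa_rate baseline daily missingness probability for the
#'   evening survey and for device wear.
#' @param ls_weekend,pa_weekend additive weekend shift of the two rates.
#' @return object of class `bvb_mar`.
#' @export
mar_config <- function(ls_rate = 0.2, pa_rate = 0.1,
                       ls_weekend = 0, pa_weekend = 0) {
  extra <- setdiff(names(match.call())[-1],
                   c("ls_rate", "pa_rate", "ls_weekend", "pa_weekend"))
  if (length(extra)) {
    stop("unknown missingness field(s): ", paste(extra, collapse = ", "),
         " (mechanisms may only use observed quantities)")
  }
  stopifnot(ls_rate >= 0, ls_rate <= 1, pa_rate >= 0, pa_rate <= 1)
  out <- list(ls_rate = ls_rate, pa_rate = pa_rate,
              ls_weekend = ls_weekend, pa_weekend = pa_weekend)
  class(out) <- "bvb_mar"
  out
}

#' Apply missing-at-random masking to a daily table
#'
#' Masks `ls_mean` and/or `pa_rate` entries according to a [mar_config()].
#' Masked entries are set to `NA` and flagged in logical columns `ls_masked`
#' and `pa_masked`; no rows are dropped.
#'
#' @param daily daily table with `person_id`, `date`, `ls_mean`, `pa_rate`.
#' @param config a [mar_config()].
#' @param seed integer seed.
#' @return the daily table with masked values and flag columns.
#' @export
apply_missingness <- function(daily, config = mar_config(), seed = 1) {
  if (!inherits(config, "bvb_mar")) stop("config must come from mar_config()")
  local_seed(seed)
  wd <- weekday_index(daily$date)
  weekend <- wd >= 6L
  p_ls <- pmin(pmax(config$ls_rate + ifelse(weekend, config$ls_weekend, 0), 0), 1)
  p_pa <- pmin(pmax(config$pa_rate + ifelse(weekend, config$pa_weekend, 0), 0), 1)
  n <- nrow(daily)
  daily$ls_masked <- stats::runif(n) < p_ls
  daily$pa_masked <- stats::runif(n) < p_pa
  daily$ls_mean[daily$ls_masked] <- NA_real_
  daily$pa_rate[daily$pa_masked] <- NA_real_
  if (!is.null(daily$wear_hours)) daily$wear_hours[daily$pa_masked] <- 0
  if (!is.null(daily$n_valid_minutes)) daily$n_valid_minutes[daily$pa_masked] <- 0L
  daily
}

#' Render observable measurement streams
#'
#' Expands realized daily measurements into (a) a minute-level wearable stream
#' with step counts, heart-rate presence and sleep flags, and (b) an evening
#' survey table with the two life-satisfaction slider items.  The daily step
#' total is distributed over a random "active" subset of worn minutes by a
#' multinomial draw, so worn zero-step minutes (valid through their heart-rate
#' reading) occur alongside stepping minutes.  Days flagged in `mask` are
#' rendered as non-wear (no worn minutes) and/or skipped surveys.
#'
#' @param latent latent series from [simulate_latent_series()] (`$latent`).
#' @param config a [render_config()].
#' @param seed integer seed.
#' @param mask optional data frame (from [apply_missingness()]) with columns
#'   `person_id`, `date`, `ls_masked`, `pa_masked`.
#' @return list with `minutes` (person_id, timestamp, steps, hr_present,
#'   asleep) and `surveys` (person_id, date, ls_item1, ls_item2).
#' @export
render_observables <- function(latent, config = render_config(), seed = 1,
                               mask = NULL) {
  meas <- realize_measurements(latent, config, seed)
  if (!is.null(mask)) {
    key <- paste(meas$person_id, meas$date)
    mk <- match(key, paste(mask$person_id, as.Date(mask$date)))
    ls_masked <- isTRUE_v(mask$ls_masked[mk])
    pa_masked <- isTRUE_v(mask$pa_masked[mk])
  } else {
    ls_masked <- pa_masked <- rep(FALSE, nrow(meas))
  }
  local_seed(seed + 1L)

  sleep_idx <- (config$sleep_start_min + seq_len(config$sleep_minutes) - 1L) %% 1440L
  wake_idx <- setdiff(0:1439, sleep_idx)

  min_list <- vector("list", nrow(meas))
  for (r in seq_len(nrow(meas))) {
    date <- meas$date[r]
    base <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
    # sleep block: worn, heart rate present, no steps
    sl <- data.frame(person_id = meas$person_id[r],
                     timestamp = base + 60 * sleep_idx,
                     steps = 0L, hr_present = TRUE, asleep = TRUE,
                     stringsAsFactors = FALSE)
    if (pa_masked[r]) { min_list[[r]] <- sl; next }
    wmin <- min(meas$wear_minutes[r], length(wake_idx))
    worn <- wake_idx[seq_len(wmin)]
    steps <- integer(wmin)
    n_active <- max(1L, round(config$active_frac * wmin))
    active <- sample.int(wmin, n_active)
    if (meas$steps_total[r] > 0) {
      steps[active] <- as.integer(stats::rmultinom(1, meas$steps_total[r],
                                                   rep(1, n_active)))
    }
    hr <- if (config$hr_dropout > 0) {
      stats::runif(wmin) >= config$hr_dropout
    } else rep(TRUE, wmin)
    wk <- data.frame(person_id = meas$person_id[r],
                     timestamp = base + 60 * worn,
                     steps = steps, hr_present = hr, asleep = FALSE,
                     stringsAsFactors = FALSE)
    min_list[[r]] <- rbind(sl, wk)
  }
  minutes <- do.call(rbind, min_list)
  minutes <- minutes[order(minutes$person_id, minutes$timestamp), ]
  rownames(minutes) <- NULL

  keep <- !ls_masked
  surveys <- data.frame(person_id = meas$person_id[keep],
                        date = meas$date[keep],
                        ls_item1 = meas$ls_item1[keep],
                        ls_item2 = meas$ls_item2[keep],
                        stringsAsFactors = FALSE)
  list(minutes = minutes, surveys = surveys)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Daily observations directly from latent values
#'
#' Fast path producing the daily observation table that preprocessing the
#' rendered minute stream and surveys would yield: the same realized wear
#' minutes, rounded daily step totals and integer slider items (via
#' `realize_measurements()`), aggregated without materializing minutes.
#' Useful for large simulation studies where the minute stream itself is not
#' of interest.
#'
#' @inheritParams render_observables
#' @return daily table with `person_id`, `date`, `ls_mean`, `pa_rate`,
#'   `wear_hours`, `n_valid_minutes`.
#' @export
observe_daily <- function(latent, config = render_config(), seed = 1) {
  meas <- realize_measurements(latent, config, seed)
  data.frame(person_id = meas$person_id, date = meas$date,
             ls_mean = (meas$ls_item1 + meas$ls_item2) / 2,
             pa_rate = meas$steps_total / (meas$wear_minutes / 60),
             wear_hours = meas$wear_minutes / 60,
             n_valid_minutes = as.integer(meas$wear_minutes),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' End-to-end orchestrator: population, burst calendar, latent VAR series,
#' realized daily observations, MAR masking and (optionally) the minute-level
#' wearable stream and survey tables consistent with the masking.
#'
#' @param n number of participants.
#' @param params a [bvb_params()] truth (default [true_parameters()]).
#' @param seed integer master seed (sub-seeds are derived from it).
#' @param population_config,render_cfg,mar_cfg stage settings.
#' @param n_bursts,burst_length,entry_start,entry_end calendar settings.
#' @param render_minutes also return minute/survey streams (memory-heavy for
#'   large n).
#' @return list with `participants`, `calendar`, `latent`, `truth` (params
#'   with realized `m`), `daily` (masked), and optionally `minutes`,
#'   `surveys`.
#' @export
simulate_study <- function(n, params = true_parameters(), seed = 1,
                           population_config = participant_config(),
                           render_cfg = render_config(),
                           mar_cfg = mar_config(),
                           n_bursts = 4, burst_length = 14,
                           entry_start = "2019-04-19", entry_end = "2021-08-31",
                           render_minutes = FALSE) {
  seed <- as.integer(seed)
  participants <- simulate_population(n, population_config, seed = seed)
  calendar <- burst_calendar(participants, entry_start, entry_end,
                             n_bursts = n_bursts, burst_length = burst_length,
                             seed = seed + 1L)
  sim <- simulate_latent_series(participants, calendar, params, seed = seed + 2L)
  daily <- observe_daily(sim$latent, render_cfg, seed = seed + 3L)
  daily <- apply_missingness(daily, mar_cfg, seed = seed + 4L)
  truth <- params
  truth$m <- sim$m
  out <- list(participants = participants, calendar = calendar,
              latent = sim$latent, truth = truth, daily = daily,
              exid_std = sim$exid_std)
  if (render_minutes) {
    streams <- render_observables(sim$latent, render_cfg, seed = seed + 3L,
                                  mask = daily)
    out$minutes <- streams$minutes
    out$surveys <- streams$surveys
  }
  out
}

#' Model-scale dataset from a simulated study
#'
#' Builds a [build_model_dataset()] object whose responses are the latent
#' model-scale values themselves (with the study's missingness mask applied),
#' bypassing the bounded measurement instrument.  This is the input used by
#' parameter-recovery studies: it isolates the estimator from the instrument
#' discretization (integer slider items, step rounding, boundary clipping),
#' whose fidelity is checked separately via round-trip tolerances.
#'
#' @param study result of [simulate_study()].
#' @param codebook optional codebook to reuse.
#' @return a `bvb_dataset` with exact latent responses where observed.
#' @export
build_latent_dataset <- function(study, codebook = NULL) {
  ds <- build_model_dataset(study$daily, study$participants, study$calendar,
                            codebook = codebook)
  key_d <- paste(ds$data$person_id, ds$data$date)
  key_l <- paste(study$latent$person_id, study$latent$date)
  m <- match(key_d, key_l)
  ds$data$L <- ifelse(is.na(ds$data$L), NA_real_, study$latent$L[m])
  ds$data$P <- ifelse(is.na(ds$data$P), NA_real_, study$latent$P[m])
  ds
}

#' Write a simulated study to plain-text files
#'
#' Writes participants, daily observations and (if present) minute and survey
#' streams as CSV, and the truth parameter set (including per-person random
#' effects) as JSON.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    p
  }
  paths <- c(paths, wr(study$participants, "participants.csv"))
  paths <- c(paths, wr(study$daily, "daily.csv"))
  paths <- c(paths, wr(study$calendar, "calendar.csv"))
  if (!is.null(study$minutes)) {
    mm <- study$minutes
    # explicit ISO-8601 so midnight does not serialize as a bare date
    mm$timestamp <- format(mm$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    paths <- c(paths, wr(mm, "minutes.csv"))
  }
  if (!is.null(study$surveys)) paths <- c(paths, wr(study$surveys, "surveys.csv"))
  tp <- file.path(dir, "truth.json")
  tr <- study$truth
  tr$beta <- as.vector(tr$beta)
  tr$m <- if (!is.null(tr$m)) list(person_id = rownames(tr$m),
                                   m_L = tr$m[, 1], m_P = tr$m[, 2])
  jsonlite::write_json(unclass(tr), tp, digits = NA, auto_unbox = TRUE)
  invisible(c(paths, tp))
}
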