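test_that("population simulation reproduces configured composition", {
  expect_error(participant_config(ses_probs = c(0.5, 0.2, 0.1)), "summing")
  expect_error(participant_config(p_female = 1.4), "\\[0, 1\\]")

  one <- simulate_population(1, seed = 5)
  expect_identical(nrow(one), 1L)
  expect_true(all(!is.na(unlist(one))))

  n <- 10000
  pop <- simulate_population(n, seed = 11)
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(pop$gender == "female") - 0.463), 3 * se(0.463))
  expect_lt(abs(mean(pop$runner) - 0.568), 3 * se(0.568))
  expect_lt(abs(mean(pop$region == "high_pollution") - 0.571), 3 * se(0.571))
  expect_true(all(pop$age >= 18 & pop$age <= 65))
  expect_true(all(pop$exid >= 9 & pop$exid <= 63))
  # runners carry systematically higher exercise identity
  expect_gt(mean(pop$exid[pop$runner]), mean(pop$exid[!pop$runner]) + 10)

  expect_identical(simulate_population(50, seed = 7),
                   simulate_population(50, seed = 7))
})

test_that("burst calendars are non-overlapping blocks of consecutive days", {
  pop <- simulate_population(8, seed = 2)
  cal <- burst_calendar(pop, seed = 3)
  expect_identical(nrow(cal), 8L * 4L)
  grid <- burstvar:::calendar_grid(cal)
  for (pid in pop$person_id) {
    g <- grid[grid$person_id == pid, ]
    expect_identical(sort(unique(g$burst)), 1:4)
    for (b in 1:4) {
      dd <- g$date[g$burst == b]
      expect_identical(length(dd), 14L)
      expect_true(all(diff(dd) == 1))
      if (b > 1) expect_gt(min(dd), max(g$date[g$burst == b - 1]))
    }
  }
  expect_error(burst_calendar(pop, burst_offsets = c(0, 10), n_bursts = 2),
               "spaced")
})

test_that("latent VAR reduces to white noise when dynamics are off", {
  pop <- simulate_population(1, seed = 1)
  cal <- burst_calendar(pop, n_bursts = 1, burst_length = 4000, seed = 1)
  delta0 <- stats::setNames(rep(0, 25), burstvar:::covariate_names())
  delta0["intercept"] <- 1.5
  pars <- bvb_params(delta_L = delta0, delta_P = delta0,
                     beta = matrix(0, 2, 2),
                     sigma_L = 0.8, sigma_P = 0.5, tau_L = 1, tau_P = 1,
                     alpha0 = 0, alpha1 = 0, m = matrix(0, 1, 2))
  sim <- simulate_latent_series(pop, cal, pars, seed = 4)
  L <- sim$latent$L
  expect_lt(abs(mean(L) - 1.5), 4 * 0.8 / sqrt(4000))
  expect_lt(abs(sd(L) - 0.8), 0.05)
  expect_lt(abs(cor(L[-1], L[-length(L)])), 0.05)
  # alpha = 0 makes same-day disturbances uncorrelated
  P <- sim$latent$P
  expect_lt(abs(cor(L, P)), 0.05)
})

test_that("latent autocorrelation matches the AR(1) truth", {
  pop <- simulate_population(1, seed = 1)
  cal <- burst_calendar(pop, n_bursts = 1, burst_length = 8000, seed = 1)
  delta0 <- stats::setNames(rep(0, 25), burstvar:::covariate_names())
  pars <- bvb_params(delta_L = delta0, delta_P = delta0,
                     beta = matrix(c(0.4, 0, 0, 0.2), 2, 2),
                     sigma_L = 1, sigma_P = 1, tau_L = 1, tau_P = 1,
                     alpha0 = 0, alpha1 = 0, m = matrix(0, 1, 2))
  sim <- simulate_latent_series(pop, cal, pars, seed = 8)
  L <- sim$latent$L
  expect_lt(abs(cor(L[-1], L[-length(L)]) - 0.4), 0.03)
})

test_that("non-stationary transition matrices are refused", {
  pop <- simulate_population(2, seed = 1)
  cal <- burst_calendar(pop, n_bursts = 1, burst_length = 14, seed = 1)
  pars <- true_parameters(beta = matrix(c(0.9, 0.5, 0.5, 0.9), 2, 2))
  expect_error(simulate_latent_series(pop, cal, pars, seed = 1),
               "not stationary")
})

test_that("bursts are dynamically independent given the random effects", {
  # with beta close to 1 within bursts, values at burst ends and next burst
  # starts decorrelate once m is removed
  pop <- simulate_population(300, seed = 6)
  cal <- burst_calendar(pop, n_bursts = 2, burst_length = 6, seed = 6)
  delta0 <- stats::setNames(rep(0, 25), burstvar:::covariate_names())
  m0 <- matrix(0, 300, 2)
  pars <- bvb_params(delta_L = delta0, delta_P = delta0,
                     beta = matrix(c(0.9, 0, 0, 0.9), 2, 2),
                     sigma_L = 1, sigma_P = 1, tau_L = 1, tau_P = 1,
                     alpha0 = 0, alpha1 = 0, m = m0)
  sim <- simulate_latent_series(pop, cal, pars, seed = 9)
  lat <- sim$latent
  ends <- lat$L[lat$burst == 1 & lat$day == 6]
  starts <- lat$L[lat$burst == 2 & lat$day == 1]
  expect_lt(abs(cor(ends, starts)), 3 / sqrt(300))
})

test_that("missingness masking is MAR, flagged and rate-calibrated", {
  st <- quick_study(n = 30, seed = 21, mar = mar_config(ls_rate = 0, pa_rate = 0))
  daily <- st$daily

  out0 <- apply_missingness(daily, mar_config(ls_rate = 0, pa_rate = 0), seed = 2)
  expect_identical(out0$ls_mean, daily$ls_mean)
  expect_identical(out0$pa_rate, daily$pa_rate)

  out <- apply_missingness(daily, mar_config(ls_rate = 0.2, pa_rate = 0.2), seed = 2)
  n <- nrow(daily)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(mean(out$ls_masked) - 0.2), 3 * se)
  expect_lt(abs(mean(out$pa_masked) - 0.2), 3 * se)
  expect_identical(nrow(out), n)  # flagged, not dropped

  # weekend-only mechanism retains every weekday entry
  wk <- apply_missingness(daily, mar_config(ls_rate = 0, pa_rate = 0,
                                            ls_weekend = 1), seed = 3)
  wd <- burstvar:::weekday_index(wk$date)
  expect_true(all(!wk$ls_masked[wd <= 5]))
  expect_true(all(wk$ls_masked[wd >= 6]))

  # a mechanism referencing the masked value itself cannot be expressed
  expect_error(mar_config(ls_value_effect = 0.5))
})

test_that("rendered streams aggregate back to the realized daily values", {
  st <- quick_study(n = 4, seed = 17, n_bursts = 1, burst_length = 6)
  streams <- render_observables(st$latent, seed = 123)
  daily_direct <- observe_daily(st$latent, seed = 123)
  daily_pre <- build_daily(streams$minutes, streams$surveys)

  key <- paste(daily_direct$person_id, daily_direct$date)
  m <- match(key, paste(daily_pre$person_id, daily_pre$date))
  expect_true(all(!is.na(m)))
  # the two paths share the realized measurements exactly
  expect_equal(daily_pre$ls_mean[m], daily_direct$ls_mean)
  expect_equal(daily_pre$pa_rate[m], daily_direct$pa_rate, tolerance = 1e-12)
  expect_equal(daily_pre$wear_hours[m], daily_direct$wear_hours)

  # round trip to the latent scale within instrument resolution
  ls_target <- pmin(pmax(inv_transform_ls(st$latent$L), 0), 100)
  pa_target <- pmax(inv_transform_pa(st$latent$P), 0)
  in_range <- inv_transform_ls(st$latent$L) >= 0 &
    inv_transform_ls(st$latent$L) <= 100
  expect_true(all(abs(daily_direct$ls_mean[in_range] -
                        ls_target[in_range]) <= 0.5))
  rel <- abs(daily_direct$pa_rate - pa_target) / pmax(pa_target, 1)
  expect_true(all(rel <= 0.01))
})

test_that("latent midpoints render to the instrument midpoints", {
  pop <- simulate_population(1, seed = 1)
  latent <- data.frame(person_id = "p0001", burst = 1L, day = 1:2,
                       date = as.Date("2020-06-01") + 0:1,
                       L = c(0, 0), P = c(0, 0), stringsAsFactors = FALSE)
  daily <- observe_daily(latent, render_config(item_offset_max = 0), seed = 2)
  expect_true(all(abs(daily$ls_mean - 50) <= 0.5))
  expect_true(all(daily$pa_rate == 0))
})

test_that("simulated studies are byte-reproducible given a seed", {
  a <- simulate_study(5, seed = 31, n_bursts = 2, burst_length = 5)
  b <- simulate_study(5, seed = 31, n_bursts = 2, burst_length = 5)
  expect_identical(a, b)
  c2 <- simulate_study(5, seed = 32, n_bursts = 2, burst_length = 5)
  expect_false(identical(a$daily$ls_mean, c2$daily$ls_mean))
})
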