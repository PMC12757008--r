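# Build a synthetic posterior-summary table whose means follow a supplied
# named vector (intervals centered on the mean with given half width).
summary_from_means <- function(means, half = 0.05) {
  data.frame(parameter = names(means), mean = unname(means),
             sd = half / 2, q2.5 = unname(means) - half,
             q97.5 = unname(means) + half, ess = 1000, rhat = 1,
             stringsAsFactors = FALSE)
}

truth_summary <- function() {
  summary_from_means(burstvar:::truth_vector(true_parameters()))
}

test_that("effect tables split into the three blocks with credible flags", {
  s <- truth_summary()
  cb <- list(columns = burstvar:::covariate_names())
  tabs <- effect_tables(s, cb)
  expect_named(tabs, c("ls_mean", "pa_mean", "dynamics"))
  expect_setequal(tabs$dynamics$variable,
                  c("sigma_L", "sigma_P", "tau_L", "tau_P", "alpha0", "alpha1",
                    "beta_LL", "beta_LP", "beta_PL", "beta_PP"))
  expect_identical(nrow(tabs$ls_mean), 25L)

  # interval spanning zero is not credible; interval excluding zero is
  s2 <- s
  s2[s2$parameter == "delta_L.age", c("q2.5", "q97.5")] <- c(-0.1, 0.2)
  s2[s2$parameter == "alpha0", c("q2.5", "q97.5")] <- c(0.0791, 0.0951)
  t2 <- effect_tables(s2, cb)
  expect_false(t2$ls_mean$credible[t2$ls_mean$variable == "age"])
  expect_true(t2$dynamics$credible[t2$dynamics$variable == "alpha0"])

  expect_error(effect_tables(s[-1, ], cb), "lacks parameter")
})

test_that("periodic profiles pin the reference at zero and find the peaks", {
  s <- truth_summary()
  pL <- periodic_profiles(s, "L")
  expect_identical(pL$weekday$level[1], "Mon")
  expect_identical(pL$weekday$mean[1], 0)
  expect_identical(attr(pL$weekday, "strongest"), "Sat")
  expect_identical(nrow(pL$month), 12L)
  expect_identical(pL$month$mean[1], 0)

  pP <- periodic_profiles(s, "P")
  expect_identical(attr(pP$month, "strongest"), "Jun")
  expect_identical(attr(pP$weekday, "strongest"), "Sat")

  flat <- s
  flat$mean[grepl("wd_|mon_", flat$parameter)] <- 0
  pf <- periodic_profiles(flat, "L")
  expect_true(all(pf$weekday$mean == 0))
})

test_that("correlation at exercise identity follows the link draw by draw", {
  draws <- cbind(alpha0 = rep(0.0872, 500), alpha1 = rep(0.0105, 500))
  ce <- correlation_at_exid(draws, exid_std = c(-1, 0, 1))
  expect_equal(round(ce$rho[ce$exid_std == 0], 3), 0.087)
  expect_lt(abs((ce$rho[3] - ce$rho[1]) - 2 * 0.0105), 1e-3)
  expect_true(all(diff(ce$rho) > 0))

  still <- cbind(alpha0 = rnorm(200, 0.1, 0.01), alpha1 = rep(0, 200))
  cs <- correlation_at_exid(still, exid_std = c(-2, 0, 2))
  expect_equal(cs$rho[1], cs$rho[2])
  expect_equal(cs$rho[2], cs$rho[3])

  # strictly increasing for every draw whenever alpha1 > 0
  set.seed(2)
  dd <- cbind(alpha0 = rnorm(100, 0, 0.3), alpha1 = runif(100, 0.01, 0.5))
  r1 <- tanh(dd[, 1] + dd[, 2] * -1)
  r2 <- tanh(dd[, 1] + dd[, 2] * 1)
  expect_true(all(r2 > r1))
})

test_that("prior sensitivity: identity pair correlates exactly 1", {
  st <- quick_study(n = 6, seed = 51, n_bursts = 1, burst_length = 6)
  ds <- build_model_dataset(st$daily, st$participants, st$calendar)
  sens <- prior_sensitivity(ds, multipliers = c(1, 1),
                            mcmc = mcmc_config(chains = 2, warmup = 40,
                                               iter = 40, seed = 4),
                            rhat_max = Inf)
  expect_identical(unname(sens$correlations), 1)
  expect_identical(unname(sens$max_abs_diff), 0)
  expect_error(prior_sensitivity(ds, multipliers = c(0.5, 2)), "baseline")
})

test_that("tiny datasets are flagged prior-dominated", {
  st <- quick_study(n = 2, seed = 53, n_bursts = 1, burst_length = 3)
  ds <- build_model_dataset(st$daily, st$participants, st$calendar)
  sens <- prior_sensitivity(ds, multipliers = c(1, 2),
                            mcmc = mcmc_config(chains = 2, warmup = 30,
                                               iter = 30, seed = 4),
                            rhat_max = Inf)
  expect_true(sens$prior_dominated)
  expect_true(is.finite(sens$correlations[["2"]]))
})

test_that("an empty recovery study returns an empty report without error", {
  rec <- recovery_study(true_parameters(), n_persons = 5, n_replicates = 0,
                        seed = 1)
  expect_identical(rec$n_replicates, 0L)
  expect_identical(nrow(rec$table), 0L)
})

test_that("effect tables round-trip through CSV exactly", {
  s <- truth_summary()
  s$mean <- s$mean + pi * 1e-9  # non-representable decimals
  cb <- list(columns = burstvar:::covariate_names())
  tabs <- effect_tables(s, cb)
  dir <- withr::local_tempdir()
  write_effect_tables(tabs, dir)
  back <- read_effect_tables(dir)
  for (nm in names(tabs)) {
    expect_identical(back[[nm]]$mean, tabs[[nm]]$mean)
    expect_identical(back[[nm]]$q2.5, tabs[[nm]]$q2.5)
    expect_identical(back[[nm]]$credible, tabs[[nm]]$credible)
  }
})
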