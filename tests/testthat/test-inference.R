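test_that("identical seeds give identical chains", {
  st <- quick_study(n = 5, seed = 23, burst_length = 6,
                    mar = mar_config(ls_rate = 0.15, pa_rate = 0.1))
  ds <- build_model_dataset(st$daily, st$participants, st$calendar)
  cfg <- mcmc_config(chains = 2, warmup = 40, iter = 40, seed = 13)
  f1 <- fit_bvar(ds, mcmc = cfg)
  f2 <- fit_bvar(ds, mcmc = cfg)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$miss_chains, f2$miss_chains)
  f3 <- fit_bvar(ds, mcmc = mcmc_config(chains = 2, warmup = 40, iter = 40,
                                        seed = 14))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("fits refuse degenerate inputs", {
  st <- quick_study(n = 4, seed = 29, burst_length = 5)
  ds <- build_model_dataset(st$daily, st$participants, st$calendar)
  ds$data$L[] <- NA
  expect_error(fit_bvar(ds), "at least one observed")
  expect_error(mcmc_config(chains = 0), "chains")
})

test_that("posterior summaries of degenerate and known draw sets", {
  # constant draws: mean c, sd 0, interval [c, c]
  cn <- c("x", "alpha0", "alpha1")
  ch <- lapply(1:2, function(i) {
    matrix(c(rep(3.5, 100), rnorm(200)), 100, 3, dimnames = list(NULL, cn))
  })
  s <- summarize_posterior(fake_fit(ch), scale = "standardized")
  r <- s[s$parameter == "x", ]
  expect_equal(r$mean, 3.5)
  expect_equal(r$sd, 0)
  expect_equal(c(r$q2.5, r$q97.5), c(3.5, 3.5))

  # large standard-normal pseudo-sample: interval close to +/- 1.96
  set.seed(31)
  big <- lapply(1:2, function(i) {
    matrix(rnorm(5e4), ncol = 1, dimnames = list(NULL, "z"))
  })
  sb <- summarize_posterior(fake_fit(big), scale = "standardized")
  expect_equal(sb$q2.5, -1.96, tolerance = 0.03)
  expect_equal(sb$q97.5, 1.96, tolerance = 0.03)
  expect_equal(sb$mean, 0, tolerance = 0.02)
})

test_that("split Rhat detects agreement and disagreement", {
  set.seed(5)
  x <- rnorm(800)
  same <- cbind(x, x, x, x)
  expect_lte(split_rhat(same), 1 + 1e-6)

  iid <- matrix(rnorm(4000), 1000, 4)
  expect_gt(split_rhat(iid), 0.99)
  expect_lt(split_rhat(iid), 1.01)

  shifted <- iid
  shifted[, 1] <- shifted[, 1] + 5
  expect_gt(split_rhat(shifted), 1.5)

  expect_true(is.na(split_rhat(matrix(rnorm(100), ncol = 1))))
  expect_identical(split_rhat(matrix(2, 50, 4)), 1)
})

test_that("bulk ESS is near the draw count for independent draws", {
  set.seed(6)
  iid <- matrix(rnorm(4000), 1000, 4)
  e <- ess_bulk(iid)
  expect_gt(e, 4000 * 0.8)
  expect_lte(e, 4000)
  # strongly autocorrelated chains have much smaller ESS
  ar <- sapply(1:4, function(i) as.numeric(arima.sim(list(ar = 0.95), 1000)))
  expect_lt(ess_bulk(ar), 1500)

  skip_if_not_installed("coda")
  ec <- sum(apply(iid, 2, function(v) coda::effectiveSize(coda::mcmc(v))))
  expect_lt(abs(e - ec) / ec, 0.25)
})

test_that("rescaling returns original-scale coefficients and preserves fits", {
  st <- quick_study(n = 8, seed = 37, burst_length = 6)
  ds <- build_model_dataset(st$daily, st$participants, st$calendar)
  fit <- fit_bvar(ds, mcmc = mcmc_config(chains = 2, warmup = 60, iter = 60,
                                         seed = 2))
  cb <- fit$codebook

  # a unit-SD zero-mean covariate would be left unchanged
  cb0 <- cb
  cb0$continuous$age <- list(mean = 0, sd = 1)
  cb0$continuous$day_in_study <- list(mean = 0, sd = 1)
  d0 <- rescale_coefficients(fit$chains[[1]], cb0)
  expect_identical(d0, fit$chains[[1]])

  # division by the stored SD (e.g. 0.19 on standardized age, SD 12.55)
  fake <- fit$chains[[1]][1:2, , drop = FALSE]
  fake[, "delta_L.age"] <- 0.19
  cb1 <- cb
  cb1$continuous$age <- list(mean = 38.09, sd = 12.55)
  rs <- rescale_coefficients(fake, cb1)
  expect_equal(unname(rs[1, "delta_L.age"]), 0.19 / 12.55, tolerance = 1e-12)
  expect_lt(abs(unname(rs[1, "delta_L.age"]) - 0.0151), 1e-4)

  # per-draw invariance of the fitted linear predictor
  raw <- encode_covariates(st$participants, ds$data,
                           codebook = cb, standardize = FALSE)
  orig <- rescale_coefficients(fit$chains[[1]], cb)
  pL <- grep("^delta_L\\.", colnames(orig))
  for (dr in c(1, 25)) {
    mu_std <- ds$X %*% fit$chains[[1]][dr, pL]
    mu_org <- raw$X %*% orig[dr, pL]
    expect_equal(max(abs(mu_std - mu_org)), 0, tolerance = 1e-10)
  }

  # name mismatches are refused
  bad <- fit$chains[[1]]
  colnames(bad)[1] <- "delta_L.wrong"
  expect_error(rescale_coefficients(bad, cb), "lack column")
})

test_that("masked fits stay close to complete-data fits (MAR robustness, small)", {
  st <- quick_study(n = 12, seed = 41, burst_length = 8)
  ds_full <- build_model_dataset(st$daily, st$participants, st$calendar)
  masked <- apply_missingness(st$daily, mar_config(ls_rate = 0.1, pa_rate = 0.1),
                              seed = 8)
  ds_miss <- build_model_dataset(masked, st$participants, st$calendar)
  cfg <- mcmc_config(chains = 2, warmup = 150, iter = 150, seed = 3)
  f_full <- fit_bvar(ds_full, mcmc = cfg)
  f_miss <- fit_bvar(ds_miss, mcmc = cfg)
  s_full <- summarize_posterior(f_full, scale = "standardized")
  s_miss <- summarize_posterior(f_miss, scale = "standardized")
  for (pn in c("beta_LL", "beta_PP", "sigma_L", "sigma_P")) {
    a <- s_full[s_full$parameter == pn, ]
    b <- s_miss[s_miss$parameter == pn, ]
    expect_lt(abs(a$mean - b$mean), 2.5 * max(a$sd, b$sd))
  }
  expect_identical(f_miss$n_divergent, 0L)
  expect_gt(f_miss$n_missing, 0L)
})
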