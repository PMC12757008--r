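test_that("moderated correlation is the inverse Fisher z link", {
  expect_equal(round(moderated_correlation(0.0872, 0.0105, 0), 3), 0.087)
  expect_identical(moderated_correlation(0, 5, 0), 0)
  r <- moderated_correlation(10, 0, 0)
  expect_gt(r, 0.9999999)
  expect_lt(r, 1)
  # image strictly inside (-1, 1), monotone, odd
  z <- seq(-8, 8, by = 0.25)
  rr <- moderated_correlation(0.3, 1, z)
  expect_true(all(rr > -1 & rr < 1))
  expect_true(all(diff(rr) > 0))
  expect_equal(moderated_correlation(0, 1, z), -moderated_correlation(0, 1, -z))
})

test_that("disturbance covariance has the stated structure", {
  expect_identical(disturbance_covariance(1, 1, 0), diag(2) * 1 +
                     matrix(0, 2, 2, dimnames = list(c("L", "P"), c("L", "P"))))
  S <- disturbance_covariance(1.2342, 0.5855, moderated_correlation(0.0872, 0, 0))
  expect_equal(S[1, 2], 0.06287, tolerance = 1e-3)
  expect_identical(S[1, 2], S[2, 1])
  rho <- 0.35
  S2 <- disturbance_covariance(1.4, 0.6, rho)
  expect_equal(det(S2), 1.4^2 * 0.6^2 * (1 - rho^2))
  expect_error(disturbance_covariance(1, 1, 1), "< 1")
  expect_error(disturbance_covariance(-1, 1, 0), "positive")
})

test_that("stationary covariance solves the Lyapunov equation", {
  E <- disturbance_covariance(1.1, 0.7, 0.2)
  expect_equal(stationary_covariance(matrix(0, 2, 2), E), unname(E),
               ignore_attr = TRUE)
  # diagonal transition: scalar AR(1) closed forms
  b <- 0.6; cc <- -0.3
  S <- stationary_covariance(diag(c(b, cc)), diag(c(2^2, 0.5^2)))
  expect_equal(diag(S), c(4 / (1 - b^2), 0.25 / (1 - cc^2)))
  expect_equal(S[1, 2], 0)

  set.seed(42)
  for (k in 1:50) {
    repeat {
      B <- matrix(runif(4, -0.8, 0.8), 2, 2)
      if (max(Mod(eigen(B)$values)) < 0.95) break
    }
    E <- disturbance_covariance(runif(1, 0.2, 2), runif(1, 0.2, 2),
                                runif(1, -0.8, 0.8))
    S <- stationary_covariance(B, E)
    expect_lt(norm(S - (B %*% S %*% t(B) + E), "F"), 1e-10)
    expect_true(all(eigen(S)$values > 0))
  }
  # agreement with iterating the recursion
  B <- matrix(c(0.5, 0.2, -0.1, 0.4), 2, 2)
  E <- disturbance_covariance(1, 0.8, 0.3)
  Sit <- E
  for (k in 1:10000) Sit <- B %*% Sit %*% t(B) + E
  expect_equal(stationary_covariance(B, E), Sit, tolerance = 1e-10)
  expect_error(stationary_covariance(matrix(c(0.9, 0.5, 0.5, 0.9), 2, 2), E),
               "not stationary")
})

test_that("log-likelihood matches the dense-Gaussian oracle", {
  set.seed(7)
  for (k in 1:60) {
    Tn <- sample(1:4, 1)
    pars <- random_toy_params()
    E <- disturbance_covariance(pars$sigma_L, pars$sigma_P,
                                moderated_correlation(pars$alpha0, pars$alpha1, 0.3))
    y <- matrix(rnorm(2 * Tn, 0, 2), Tn, 2)
    ds <- toy_dataset(y[, 1], y[, 2])
    mu <- cbind(rep(pars$delta_L, Tn), rep(pars$delta_P, Tn))
    ll <- log_likelihood(ds, pars, include_ranef_prior = FALSE)
    oracle <- dense_loglik_oracle(y, mu, pars$m[1, ], pars$beta, E)
    expect_equal(ll, as.numeric(oracle), tolerance = 1e-8)
  }
})

test_that("log-likelihood factorizes when dynamics and correlation vanish", {
  set.seed(8)
  Tn <- 6
  y <- matrix(rnorm(2 * Tn), Tn, 2)
  ds <- toy_dataset(y[, 1], y[, 2])
  pars <- bvb_params(delta_L = c(intercept = 0.4), delta_P = c(intercept = -0.2),
                     beta = matrix(0, 2, 2), sigma_L = 1.3, sigma_P = 0.6,
                     tau_L = 1, tau_P = 1, alpha0 = 0, alpha1 = 0,
                     m = matrix(0, 1, 2))
  ll <- log_likelihood(ds, pars, include_ranef_prior = FALSE)
  expect_equal(ll, sum(dnorm(y[, 1], 0.4, 1.3, log = TRUE)) +
                 sum(dnorm(y[, 2], -0.2, 0.6, log = TRUE)))
})

test_that("log-likelihood is invariant to person ordering and matches C++", {
  st <- quick_study(n = 8, seed = 15)
  ds <- build_model_dataset(st$daily, st$participants, st$calendar)
  pars <- st$truth
  ll_r <- log_likelihood(ds, pars, include_ranef_prior = FALSE)

  # permute person blocks
  d <- ds$data
  ord <- order(match(d$person_id, rev(ds$persons)), d$burst, d$day)
  ds2 <- ds
  ds2$data <- d[ord, ]
  ds2$X <- ds$X[ord, , drop = FALSE]
  ds2$persons <- rev(ds$persons)
  ds2$exid_std <- ds$exid_std[ds2$persons]
  pars2 <- pars
  pars2$m <- pars$m[rev(seq_len(nrow(pars$m))), , drop = FALSE]
  expect_equal(log_likelihood(ds2, pars2, include_ranef_prior = FALSE), ll_r)

  # compiled likelihood used inside the sampler agrees with the R reference
  pidx <- match(d$person_id, ds$persons)
  mu <- cbind(ds$X %*% pars$delta_L, ds$X %*% pars$delta_P)
  W <- cbind(d$L, d$P) - mu - pars$m[pidx, ]
  prevrow <- ifelse(d$lag_available, seq_len(nrow(d)) - 2L, -1L)
  ll_cpp <- burstvar:::.bvb_loglik_resid(W, pidx - 1L, prevrow,
                                         unname(ds$exid_std), pars$beta,
                                         pars$sigma_L, pars$sigma_P,
                                         pars$alpha0, pars$alpha1, 0L)
  expect_equal(ll_cpp, ll_r, tolerance = 1e-10)
})

test_that("log-prior support and scale behaviour are correct", {
  pars <- true_parameters()
  pars$m <- matrix(0, 1, 2)
  lp1 <- log_prior(pars, prior_config(sigma_scale = 1, tau_scale = 1,
                                      coef_sd = Inf))
  expect_true(is.finite(lp1))

  bad <- pars
  bad$beta[1, 1] <- 1.2
  expect_identical(log_prior(bad), -Inf)
  bad2 <- pars
  bad2$sigma_L <- -0.1
  expect_identical(log_prior(bad2), -Inf)

  # doubling every half-normal scale shifts the log prior by the closed form:
  # per parameter, -log 2 + (3/8) (x / s)^2
  lp2 <- log_prior(pars, prior_config(sigma_scale = 1, tau_scale = 1,
                                      multiplier = 2, coef_sd = Inf))
  vals <- c(pars$sigma_L, pars$sigma_P, pars$tau_L, pars$tau_P)
  expect_equal(lp2 - lp1, sum(-log(2) + (3 / 8) * (vals / 1)^2))

  # improper-flat vs wide-normal fallback differ by the normal terms
  lp3 <- log_prior(pars, prior_config(sigma_scale = 1, tau_scale = 1,
                                      coef_sd = 50))
  coefs <- c(pars$delta_L, pars$delta_P, pars$alpha0, pars$alpha1)
  expect_equal(lp3 - lp1, sum(dnorm(coefs, 0, 50, log = TRUE)))
})
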