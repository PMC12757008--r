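# Shared fixtures and independent oracles for the test suite.

# Minimal model dataset for one person, one burst, with arbitrary responses
# and covariate matrix (defaults to intercept-only).
toy_dataset <- function(L, P, X = NULL, exid_std = 0.3, person = "p1") {
  Tn <- length(L)
  if (is.null(X)) {
    X <- matrix(1, Tn, 1, dimnames = list(NULL, "intercept"))
  }
  df <- data.frame(
    person_id = person, burst = 1L, day = seq_len(Tn),
    date = as.Date("2020-01-06") + seq_len(Tn) - 1L,
    L = L, P = P, lag_available = seq_len(Tn) > 1L,
    stringsAsFactors = FALSE
  )
  structure(list(data = df, X = X,
                 exid_std = stats::setNames(exid_std, person),
                 codebook = NULL, persons = person),
            class = "bvb_dataset")
}

# Dense-Gaussian oracle: the joint log density of a single stationary
# VAR(1) burst, assembled from first principles.  y, mu are T x 2 matrices;
# cross-covariance blocks are Cov(y_t, y_s) = B^(t-s) S for t >= s.
dense_loglik_oracle <- function(y, mu, m, B, E) {
  Tn <- nrow(y)
  S <- stationary_covariance(B, E)
  Bpow <- vector("list", Tn)
  Bpow[[1]] <- diag(2)
  if (Tn > 1) for (k in 2:Tn) Bpow[[k]] <- Bpow[[k - 1]] %*% B
  C <- matrix(0, 2 * Tn, 2 * Tn)
  for (t in seq_len(Tn)) {
    for (s in seq_len(t)) {
      blk <- Bpow[[t - s + 1]] %*% S
      C[(2 * t - 1):(2 * t), (2 * s - 1):(2 * s)] <- blk
      C[(2 * s - 1):(2 * s), (2 * t - 1):(2 * t)] <- t(blk)
    }
  }
  r <- as.vector(t(y - mu - matrix(m, Tn, 2, byrow = TRUE)))
  -Tn * log(2 * pi) - 0.5 * determinant(C, logarithm = TRUE)$modulus -
    0.5 * sum(r * solve(C, r))
}

# Random valid parameter set for an intercept-only toy dataset.
random_toy_params <- function() {
  repeat {
    B <- matrix(stats::runif(4, -0.7, 0.7), 2, 2)
    if (max(Mod(eigen(B, only.values = TRUE)$values)) < 0.95) break
  }
  bvb_params(
    delta_L = c(intercept = stats::rnorm(1)),
    delta_P = c(intercept = stats::rnorm(1)),
    beta = B,
    sigma_L = stats::runif(1, 0.3, 2), sigma_P = stats::runif(1, 0.3, 2),
    tau_L = stats::runif(1, 0.2, 1.5), tau_P = stats::runif(1, 0.2, 1.5),
    alpha0 = stats::rnorm(1, 0, 0.5), alpha1 = stats::rnorm(1, 0, 0.3),
    m = matrix(stats::rnorm(2, 0, 0.8), 1, 2)
  )
}

# Small complete (no missingness) simulated study for fit-level tests.
quick_study <- function(n = 10, seed = 99, n_bursts = 2, burst_length = 8,
                        mar = mar_config(ls_rate = 0, pa_rate = 0)) {
  simulate_study(n, seed = seed, n_bursts = n_bursts,
                 burst_length = burst_length, mar_cfg = mar)
}

# Fake fit object holding externally supplied chains, for testing the
# summary/diagnostic path in isolation from the sampler.
fake_fit <- function(chains) {
  structure(list(chains = chains, miss_chains = list(),
                 param_names = colnames(chains[[1]]),
                 codebook = NULL, persons = character(0),
                 priors = prior_config(), mcmc = mcmc_config(),
                 first_day = "stationary", n_divergent = 0L,
                 nonstationary_hits = 0, n_missing = 0L),
            class = "bvb_fit")
}
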