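#' Moderated contemporaneous correlation
#'
#' The same-day correlation between the two VAR disturbances is linked to the
#' exercise-identity moderator through the inverse Fisher z transformation:
#' `rho = tanh(alpha0 + alpha1 * exid_std)`.  The link keeps the correlation
#' strictly inside (-1, 1) for any real coefficients, is strictly increasing
#' in its argument, and `alpha0` is the link-scale correlation for a person of
#' average exercise identity (the moderator enters standardized).
#'
#' @param alpha0,alpha1 link-scale intercept and slope.
#' @param exid_std standardized exercise-identity score(s).
#' @return correlation value(s) in (-1, 1).
#' @examples
#' moderated_correlation(0.0872, 0.0105, 0)  # ~0.087
#' @export
moderated_correlation <- function(alpha0, alpha1, exid_std) {
  stopifnot(is.finite(alpha0), is.finite(alpha1), all(is.finite(exid_std)))
  tanh(alpha0 + alpha1 * exid_std)
}

#' Disturbance covariance matrix
#'
#' Assembles the 2x2 covariance of the same-day VAR disturbances from the two
#' marginal standard deviations and the (possibly moderated) correlation:
#' diagonal `sigma_L^2`, `sigma_P^2`, off-diagonal `sigma_L * sigma_P * rho`.
#'
#' @param sigma_L,sigma_P positive disturbance SDs for the L and P equations.
#' @param rho correlation in (-1, 1).
#' @return symmetric positive-definite 2x2 matrix (rows/cols `L`, `P`).
#' @export
disturbance_covariance <- function(sigma_L, sigma_P, rho) {
  if (sigma_L <= 0 || sigma_P <= 0) stop("sigma_L and sigma_P must be positive")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  off <- sigma_L * sigma_P * rho
  matrix(c(sigma_L^2, off, off, sigma_P^2), 2, 2,
         dimnames = list(c("L", "P"), c("L", "P")))
}

# Spectral radius of a 2x2 (or general) matrix.
spectral_radius <- function(beta) {
  max(Mod(eigen(beta, only.values = TRUE)$values))
}

#' Stationary covariance of the VAR(1)
#'
#' Solves the discrete Lyapunov equation `S = B S B' + Sigma_eps` for the
#' time-invariant covariance of a stationary first-order VAR, via the
#' vectorized linear system `(I - B (x) B) vec(S) = vec(Sigma_eps)`.  Used to
#' initialize the first day of each burst and to give burst-first days a
#' likelihood contribution.
#'
#' @param beta 2x2 transition matrix with spectral radius < 1.
#' @param sigma_mat 2x2 disturbance covariance (see [disturbance_covariance()]).
#' @return symmetric positive-definite 2x2 matrix.
#' @export
stationary_covariance <- function(beta, sigma_mat) {
  beta <- as.matrix(beta)
  if (spectral_radius(beta) >= 1) {
    stop("transition matrix is not stationary (spectral radius >= 1)")
  }
  k <- nrow(beta)
  A <- diag(k * k) - kronecker(beta, beta)
  S <- matrix(solve(A, as.vector(sigma_mat)), k, k,
              dimnames = dimnames(sigma_mat))
  (S + t(S)) / 2
}

#' Model parameter sets
#'
#' A `bvb_params` object collects every unknown of the model: mean-model
#' coefficient vectors `delta_L` and `delta_P` (named by [covariate_names()]),
#' the 2x2 transition matrix `beta` (entry `beta[i, j]` is the effect of
#' yesterday's variable `j` on today's variable `i`), disturbance SDs
#' `sigma_L`, `sigma_P`, random-intercept SDs `tau_L`, `tau_P`, the
#' correlation-link coefficients `alpha0`, `alpha1`, and (optionally)
#' per-person random intercepts `m` (a 2-column matrix, columns `L`, `P`).
#' The same container serves as simulation truth and as a posterior draw.
#'
#' @param delta_L,delta_P named numeric coefficient vectors.
#' @param beta 2x2 numeric matrix, entries in (-1, 1).
#' @param sigma_L,sigma_P,tau_L,tau_P positive scalars.
#' @param alpha0,alpha1 real scalars.
#' @param m optional matrix of per-person random intercepts (columns L, P).
#' @return object of class `bvb_params`.
#' @export
bvb_params <- function(delta_L, delta_P, beta,
                       sigma_L, sigma_P, tau_L, tau_P,
                       alpha0, alpha1, m = NULL) {
  beta <- matrix(as.numeric(beta), 2, 2,
                 dimnames = list(c("L", "P"), c("L", "P")))
  if (any(abs(beta) >= 1)) stop("all entries of beta must lie strictly in (-1, 1)")
  if (any(c(sigma_L, sigma_P, tau_L, tau_P) <= 0)) {
    stop("sigma and tau parameters must be strictly positive")
  }
  stopifnot(is.finite(alpha0), is.finite(alpha1))
  out <- list(delta_L = delta_L, delta_P = delta_P, beta = beta,
              sigma_L = sigma_L, sigma_P = sigma_P,
              tau_L = tau_L, tau_P = tau_P,
              alpha0 = alpha0, alpha1 = alpha1, m = m)
  class(out) <- "bvb_params"
  out
}

#' Prior configuration
#'
#' The mean-model and correlation-link coefficients carry uniform (improper
#' flat) priors with no range restriction; the VAR transition entries carry
#' uniform priors on (-1, 1); the disturbance and random-effect SDs carry
#' half-normal priors.  `multiplier` scales all half-normal SDs at once (the
#' handle used by the prior-sensitivity analysis, e.g. 0.5 / 1 / 2).
#' `coef_sd` is a proper wide-normal fallback for the flat coefficient priors,
#' used by samplers that require a proper posterior; `Inf` keeps the prior
#' flat.
#'
#' @param sigma_scale,tau_scale half-normal scale for the disturbance and
#'   random-effect SDs.  The default of 2 is weakly informative on the
#'   transformed-response scale, where daily disturbance and random-intercept
#'   SDs are of order 0.4-1.3: the prior density is nearly flat over the
#'   plausible range, matching the flat-prior spirit of the model.
#' @param coef_sd SD of the wide-normal fallback prior for regression and
#'   alpha coefficients (`Inf` = improper flat).
#' @param multiplier common multiplier applied to both half-normal scales.
#' @return object of class `bvb_priors`.
#' @export
prior_config <- function(sigma_scale = 2, tau_scale = 2,
                         coef_sd = 50, multiplier = 1) {
  stopifnot(sigma_scale > 0, tau_scale > 0, coef_sd > 0, multiplier > 0)
  out <- list(sigma_scale = sigma_scale * multiplier,
              tau_scale = tau_scale * multiplier,
              coef_sd = coef_sd)
  class(out) <- "bvb_priors"
  out
}

half_normal_logpdf <- function(x, scale) {
  if (x < 0) return(-Inf)
  log(2) - 0.5 * log(2 * pi) - log(scale) - 0.5 * (x / scale)^2
}

#' Log-prior density
#'
#' Evaluates the joint log prior of a parameter set under a [prior_config()]:
#' `-Inf` outside the support (any `|beta| >= 1`, any non-positive SD),
#' half-normal terms for `sigma` and `tau`, uniform contributions (zero, or
#' wide-normal if `coef_sd` is finite) for the coefficient blocks.  Random
#' effects are not part of the prior; their exchangeable normal density is
#' accounted for separately (see [log_likelihood()] details).
#'
#' @param params a [bvb_params()] object.
#' @param priors a [prior_config()] object.
#' @return scalar log density (possibly `-Inf`).
#' @export
log_prior <- function(params, priors = prior_config()) {
  if (any(abs(params$beta) >= 1)) return(-Inf)
  if (any(c(params$sigma_L, params$sigma_P, params$tau_L, params$tau_P) <= 0)) {
    return(-Inf)
  }
  lp <- half_normal_logpdf(params$sigma_L, priors$sigma_scale) +
    half_normal_logpdf(params$sigma_P, priors$sigma_scale) +
    half_normal_logpdf(params$tau_L, priors$tau_scale) +
    half_normal_logpdf(params$tau_P, priors$tau_scale)
  if (is.finite(priors$coef_sd)) {
    coefs <- c(params$delta_L, params$delta_P, params$alpha0, params$alpha1)
    lp <- lp + sum(stats::dnorm(coefs, 0, priors$coef_sd, log = TRUE))
  }
  lp
}

dmvnorm2 <- function(u, S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  q <- (S[2, 2] * u[1]^2 - 2 * S[1, 2] * u[1] * u[2] + S[1, 1] * u[2]^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Observed-data log-likelihood of the VAR model
#'
#' Reference (pure R) evaluation of the model log-likelihood for a complete
#' parameter set, summing over persons, bursts and days.  Burst-first days
#' (and days whose predecessor is unobserved in either component) contribute
#' through the stationary marginal centered at `mu + m`; all other days
#' contribute the VAR(1) transition density with the person-specific
#' disturbance covariance implied by the moderated correlation.  Days with a
#' missing component contribute the corresponding (conditional) Gaussian
#' marginal of the observed component, the observed-data likelihood under
#' missingness at random.  Setting `first_day = "condition"` drops the
#' burst-first marginal terms instead (conditioning on the first observation).
#'
#' With `include_ranef_prior = TRUE` the exchangeable normal density of the
#' supplied random effects is added, so that
#' `log_likelihood + log_prior` is the full (unnormalized) log posterior.
#'
#' @param dataset a [build_model_dataset()] object.
#' @param params a [bvb_params()] object with per-person `m` (rows in the
#'   order of `dataset$persons`).
#' @param first_day `"stationary"` (default) or `"condition"`.
#' @param include_ranef_prior add the N(0, tau^2) density of the random
#'   effects (default `TRUE`).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(dataset, params,
                           first_day = c("stationary", "condition"),
                           include_ranef_prior = TRUE) {
  first_day <- match.arg(first_day)
  d <- dataset$data
  X <- dataset$X
  if (is.null(params$m)) stop("params$m (per-person random effects) is required")
  m <- as.matrix(params$m)
  if (nrow(m) != length(dataset$persons)) {
    stop("params$m must have one row per person in the dataset")
  }
  pidx <- match(d$person_id, dataset$persons)

  mu <- cbind(X %*% params$delta_L, X %*% params$delta_P)
  W <- cbind(d$L, d$P) - mu - m[pidx, , drop = FALSE]

  rho <- moderated_correlation(params$alpha0, params$alpha1, dataset$exid_std)
  B <- params$beta
  if (spectral_radius(B) >= 1) return(-Inf)

  ll <- 0
  for (r in seq_len(nrow(d))) {
    i <- pidx[r]
    E <- disturbance_covariance(params$sigma_L, params$sigma_P, rho[i])
    is_first <- !d$lag_available[r] ||
      any(is.na(W[r - 1L, ]))  # unobserved predecessor: fall back to marginal
    if (is_first) {
      if (first_day == "condition") next
      S <- stationary_covariance(B, E)
      u <- W[r, ]
      ll <- ll + partial_gaussian_logpdf(u, S)
    } else {
      u <- W[r, ] - as.vector(B %*% W[r - 1L, ])
      ll <- ll + partial_gaussian_logpdf(u, E)
    }
  }
  if (include_ranef_prior) {
    ll <- ll + sum(stats::dnorm(m[, 1], 0, params$tau_L, log = TRUE)) +
      sum(stats::dnorm(m[, 2], 0, params$tau_P, log = TRUE))
  }
  ll
}

# Gaussian log density of the observed components of a 2-vector with
# possibly missing entries (marginalization under MAR).
partial_gaussian_logpdf <- function(u, S) {
  obs <- !is.na(u)
  if (!any(obs)) return(0)
  if (all(obs)) return(dmvnorm2(u, S))
  j <- which(obs)
  stats::dnorm(u[j], 0, sqrt(S[j, j]), log = TRUE)
}
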