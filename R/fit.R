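# Model fitting by MCMC, convergence diagnostics, coefficient rescaling and
# posterior summaries.

#' MCMC configuration
#'
#' Settings for [fit_bvar()].  The package's sampler is a blocked Gibbs
#' sampler (collapsed coefficient block, conjugate random-effect and
#' missing-value updates, slice sampling for the remaining scalars); it has
#' no divergent transitions and no step-size adaptation.  `target_accept` and
#' `max_treedepth` are accepted and recorded for interoperability with
#' gradient-based (Hamiltonian) backends but do not influence the Gibbs
#' sampler.
#'
#' @param chains number of independent chains (>= 2 for Rhat).
#' @param warmup discarded warmup iterations per chain.
#' @param iter retained sampling iterations per chain.
#' @param seed integer seed; chain c uses `seed + c`.
#' @param target_accept,max_treedepth recorded, inert for the Gibbs backend.
#' @return object of class `bvb_mcmc`.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, iter = 1000, seed = 1,
                        target_accept = 0.9, max_treedepth = 10) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 1,
            target_accept > 0, target_accept < 1, max_treedepth >= 1)
  out <- list(chains = as.integer(chains), warmup = as.integer(warmup),
              iter = as.integer(iter), seed = as.integer(seed),
              target_accept = target_accept,
              max_treedepth = as.integer(max_treedepth))
  class(out) <- "bvb_mcmc"
  out
}

fit_param_names <- function(dataset) {
  cn <- colnames(dataset$X)
  c(paste0("delta_L.", cn), paste0("delta_P.", cn),
    "beta_LL", "beta_LP", "beta_PL", "beta_PP",
    "sigma_L", "sigma_P", "alpha0", "alpha1", "tau_L", "tau_P",
    paste0("m_L.", dataset$persons), paste0("m_P.", dataset$persons))
}

#' Fit the hierarchical bivariate VAR model
#'
#' Estimates all model parameters jointly by MCMC: mean-model coefficients
#' for both responses (on the standardized covariate scale internally), the
#' 2x2 transition matrix, disturbance SDs, the correlation-link coefficients,
#' random-effect SDs, per-person random intercepts, and latent values for
#' every missing response (full-information estimation under missingness at
#' random).  Burst-first days contribute through the stationary marginal of
#' the VAR by default; `first_day = "condition"` conditions on them instead.
#'
#' @param dataset a [build_model_dataset()] object.
#' @param priors a [prior_config()].
#' @param mcmc a [mcmc_config()].
#' @param first_day `"stationary"` (default) or `"condition"`.
#' @return object of class `bvb_fit`: per-chain draw matrices (named
#'   columns), latent missing-value draws, the dataset codebook, sampler
#'   diagnostics counters (`n_divergent` is structurally zero for the Gibbs
#'   backend; `nonstationary_hits` counts slice evaluations rejected because
#'   the proposed transition matrix was non-stationary) and the
#'   configuration used.
#' @export
fit_bvar <- function(dataset, priors = prior_config(), mcmc = mcmc_config(),
                     first_day = c("stationary", "condition")) {
  first_day <- match.arg(first_day)
  stopifnot(inherits(dataset, "bvb_dataset"))
  d <- dataset$data
  if (nrow(d) == 0) stop("empty dataset")
  Y <- cbind(d$L, d$P)
  obs <- !is.na(Y)
  if (!any(obs[, 1]) || !any(obs[, 2])) {
    stop("need at least one observed value per response")
  }
  if (any(!is.finite(Y[obs]))) stop("non-finite observed responses")

  person <- match(d$person_id, dataset$persons) - 1L
  rowix <- seq_len(nrow(d))
  prevrow <- ifelse(d$lag_available, rowix - 2L, -1L)

  miss_rows <- which(!obs[, 1] | !obs[, 2])
  miss_which <- (!obs[miss_rows, 1]) * 1L + (!obs[miss_rows, 2]) * 2L

  # fill missing responses with the person's observed mean (column mean backup)
  Yf <- Y
  for (j in 1:2) {
    cm <- stats::ave(Y[, j], d$person_id,
                     FUN = function(v) mean(v, na.rm = TRUE))
    cm[!is.finite(cm)] <- mean(Y[, j], na.rm = TRUE)
    Yf[is.na(Y[, j]), j] <- cm[is.na(Y[, j])]
  }

  X <- dataset$X
  p <- ncol(X)
  np <- length(dataset$persons)
  pri <- list(sigma_scale = priors$sigma_scale, tau_scale = priors$tau_scale,
              coef_sd = priors$coef_sd)
  mode <- if (first_day == "stationary") 0L else 1L

  # moment-based center for overdispersed chain starts
  ridge <- diag(1e-6, p)
  XtX <- crossprod(X) + ridge
  base_delta <- c(solve(XtX, crossprod(X, Yf[, 1])),
                  solve(XtX, crossprod(X, Yf[, 2])))
  res_sd <- pmax(c(stats::sd(Yf[, 1] - X %*% base_delta[1:p]),
                   stats::sd(Yf[, 2] - X %*% base_delta[p + 1:p])), 0.05)

  chains <- vector("list", mcmc$chains)
  miss_chains <- vector("list", mcmc$chains)
  nonstat <- 0
  for (ch in seq_len(mcmc$chains)) {
    local_seed(mcmc$seed + ch)
    init <- list(
      delta = base_delta + stats::rnorm(2 * p, 0, 0.1),
      m = matrix(0, np, 2),
      beta = c(stats::runif(1, 0, 0.6), stats::runif(1, -0.15, 0.15),
               stats::runif(1, -0.15, 0.15), stats::runif(1, 0, 0.6)),
      sigma_L = res_sd[1] * exp(stats::rnorm(1, 0, 0.2)),
      sigma_P = res_sd[2] * exp(stats::rnorm(1, 0, 0.2)),
      tau_L = 0.7 * res_sd[1] * exp(stats::rnorm(1, 0, 0.2)),
      tau_P = 0.7 * res_sd[2] * exp(stats::rnorm(1, 0, 0.2)),
      alpha0 = stats::rnorm(1, 0, 0.2),
      alpha1 = stats::rnorm(1, 0, 0.1)
    )
    res <- .bvb_gibbs(Yf, X, person, prevrow, dataset$exid_std,
                      miss_rows - 1L, miss_which, pri, mode,
                      mcmc$warmup, mcmc$iter, init)
    dm <- res$draws
    colnames(dm) <- fit_param_names(dataset)
    chains[[ch]] <- dm
    miss_chains[[ch]] <- res$miss_draws
    nonstat <- nonstat + res$nonstationary_hits
  }

  out <- list(chains = chains, miss_chains = miss_chains,
              param_names = fit_param_names(dataset),
              codebook = dataset$codebook, persons = dataset$persons,
              priors = priors, mcmc = mcmc, first_day = first_day,
              n_divergent = 0L, nonstationary_hits = nonstat,
              n_missing = length(miss_rows))
  class(out) <- "bvb_fit"
  out
}

#' @export
print.bvb_fit <- function(x, ...) {
  cat("<bvb_fit> ", length(x$chains), " chains x ", nrow(x$chains[[1]]),
      " iterations (", x$mcmc$warmup, " warmup), ",
      length(x$param_names), " parameters, ", x$n_missing,
      " missing person-days\n", sep = "")
  dg <- diagnose(x)
  cat("  max split-Rhat ", round(dg$max_rhat, 4), ", min bulk-ESS ",
      round(dg$min_ess), ", divergent transitions ", dg$n_divergent,
      "\n", sep = "")
  invisible(x)
}

# ---- convergence diagnostics -------------------------------------------------

rank_normalize <- function(mat) {
  S <- length(mat)
  z <- stats::qnorm((rank(as.vector(mat), ties.method = "average") - 3 / 8) /
                      (S + 1 / 4))
  matrix(z, nrow(mat), ncol(mat))
}

split_chains <- function(mat) {
  n <- nrow(mat)
  h <- n %/% 2L
  if (h < 1L) return(mat)
  cbind(mat[seq_len(h), , drop = FALSE],
        mat[(n - h + 1L):n, , drop = FALSE])
}

rhat_basic <- function(mat) {
  n <- nrow(mat)
  M <- ncol(mat)
  if (n < 2L || M < 2L) return(NA_real_)
  means <- colMeans(mat)
  vars <- apply(mat, 2, stats::var)
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt((n - 1) / n + B_over_n / W)
}

#' Split rank-normalized Rhat
#'
#' Potential-scale-reduction diagnostic computed on rank-normalized split
#' chains, taking the larger of the bulk statistic and the folded statistic
#' (tail sensitivity).  Values near 1 indicate the chains agree.
#'
#' @param mat iterations x chains matrix of draws for one parameter.
#' @return scalar Rhat (NA for a single chain; 1 for exactly constant draws).
#' @export
split_rhat <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) return(NA_real_)
  if (stats::sd(as.vector(mat)) == 0) return(1)
  sp <- split_chains(mat)
  bulk <- rhat_basic(rank_normalize(sp))
  folded <- rhat_basic(rank_normalize(abs(sp - stats::median(sp))))
  max(bulk, folded, na.rm = TRUE)
}

autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  L <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, L - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / (L * n)
  ac
}

#' Bulk effective sample size
#'
#' Effective sample size of rank-normalized split chains, combining
#' within-chain autocovariances with Geyer's initial monotone positive
#' sequence estimator.
#'
#' @param mat iterations x chains matrix of draws for one parameter.
#' @return scalar ESS (NA for degenerate input), at most the total number of
#'   draws.
#' @export
ess_bulk <- function(mat) {
  mat <- as.matrix(mat)
  if (stats::sd(as.vector(mat)) == 0) return(NA_real_)
  z <- rank_normalize(split_chains(mat))
  n <- nrow(z)
  M <- ncol(z)
  if (n < 4L) return(NA_real_)
  acov <- sapply(seq_len(M), function(j) autocov_fft(z[, j]))
  mean_acov <- rowMeans(acov)
  W <- mean(apply(z, 2, stats::var))
  var_plus <- (n - 1) / n * W +
    (if (M > 1) stats::var(colMeans(z)) else 0)
  if (var_plus <= 0) return(NA_real_)
  rho <- 1 - (W - mean_acov) / var_plus
  rho[1] <- 1
  # Geyer initial monotone positive sequence on paired sums
  max_pairs <- floor((n - 1) / 2)
  tau <- 0
  prev <- Inf
  for (k in 0:max_pairs) {
    i1 <- 2 * k + 1
    i2 <- 2 * k + 2
    if (i2 > length(rho)) break
    pair <- rho[i1] + rho[i2]
    if (k > 0 && pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + pair
  }
  tau <- max(2 * tau - 1, 1 / log10(n * M + 10))
  min(n * M / tau, n * M)
}

#' Convergence report
#'
#' Split rank-normalized Rhat and bulk ESS for every recorded model
#' parameter, plus sampler counters.  Latent missing-value draws are not part
#' of the parameter diagnostics; per-person random effects are included by
#' default.
#'
#' @param fit a [fit_bvar()] object.
#' @param include_ranef include the per-person random intercepts (default
#'   `TRUE`).
#' @return list with `table` (parameter, rhat, ess), `max_rhat`, `min_ess`,
#'   `n_divergent`, `nonstationary_hits`, `n_chains`.
#' @export
diagnose <- function(fit, include_ranef = TRUE) {
  stopifnot(inherits(fit, "bvb_fit"))
  pn <- fit$param_names
  if (!include_ranef) pn <- pn[!grepl("^m_[LP]\\.", pn)]
  single <- length(fit$chains) < 2L
  tab <- data.frame(parameter = pn,
                    rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(pn)) {
    mat <- sapply(fit$chains, function(ch) ch[, pn[k]])
    tab$rhat[k] <- if (single) NA_real_ else split_rhat(mat)
    tab$ess[k] <- ess_bulk(mat)
  }
  list(table = tab,
       max_rhat = if (single) NA_real_ else
         suppressWarnings(max(tab$rhat, na.rm = TRUE)),
       min_ess = suppressWarnings(min(tab$ess, na.rm = TRUE)),
       n_divergent = fit$n_divergent,
       nonstationary_hits = fit$nonstationary_hits,
       n_chains = length(fit$chains))
}

# ---- coefficient rescaling ---------------------------------------------------

#' Rescale coefficient draws to the original covariate scale
#'
#' Covariates are standardized before fitting; this maps every draw back to
#' the original scale: a coefficient on a standardized covariate is divided
#' by the covariate's stored SD, and the intercept absorbs the centering so
#' the fitted linear predictor is unchanged draw by draw.  Indicator
#' coefficients and all non-regression parameters pass through untouched
#' (the correlation-link coefficients stay on the standardized
#' exercise-identity scale, where `alpha0` is the link-scale correlation at
#' average exercise identity).
#'
#' @param draws draw matrix with named columns (one chain), or a `bvb_fit`.
#' @param codebook the dataset codebook (taken from the fit if omitted).
#' @return object of the same shape with rescaled columns.
#' @export
rescale_coefficients <- function(draws, codebook = NULL) {
  if (inherits(draws, "bvb_fit")) {
    fit <- draws
    fit$chains <- lapply(fit$chains, rescale_coefficients, codebook = fit$codebook)
    return(fit)
  }
  if (is.null(codebook)) stop("codebook is required to rescale a draw matrix")
  cn <- colnames(draws)
  for (resp in c("L", "P")) {
    ic <- paste0("delta_", resp, ".intercept")
    if (!ic %in% cn) stop("draws lack column ", ic, "; name mismatch with codebook")
    for (nm in c("day_in_study", "age")) {
      cc <- paste0("delta_", resp, ".", nm)
      if (!cc %in% cn) stop("draws lack column ", cc)
      cb <- codebook$continuous[[nm]]
      draws[, ic] <- draws[, ic] - draws[, cc] * cb$mean / cb$sd
      draws[, cc] <- draws[, cc] / cb$sd
    }
  }
  draws
}

# ---- posterior summaries -----------------------------------------------------

#' Posterior summary table
#'
#' Per-parameter posterior mean, SD, central 95% credible interval, bulk ESS
#' and split Rhat, pooling all chains.  With `scale = "original"` (default)
#' mean-model coefficients are reported on the original covariate scale.
#'
#' @param fit a [fit_bvar()] object.
#' @param scale `"original"` or `"standardized"` for the coefficient blocks.
#' @param include_ranef include per-person random intercepts (default
#'   `FALSE`: summaries focus on structural parameters).
#' @return data frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`, `ess`, `rhat`.
#' @export
summarize_posterior <- function(fit, scale = c("original", "standardized"),
                                include_ranef = FALSE) {
  scale <- match.arg(scale)
  stopifnot(inherits(fit, "bvb_fit"))
  chains <- fit$chains
  if (scale == "original") {
    chains <- lapply(chains, rescale_coefficients, codebook = fit$codebook)
  }
  pn <- colnames(chains[[1]])
  if (!include_ranef) pn <- pn[!grepl("^m_[LP]\\.", pn)]
  single <- length(chains) < 2L
  out <- data.frame(parameter = pn, mean = NA_real_, sd = NA_real_,
                    q2.5 = NA_real_, q97.5 = NA_real_, ess = NA_real_,
                    rhat = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(pn)) {
    mat <- sapply(chains, function(ch) ch[, pn[k]])
    v <- as.vector(mat)
    out$mean[k] <- mean(v)
    out$sd[k] <- stats::sd(v)
    qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    out$q2.5[k] <- qs[1]
    out$q97.5[k] <- qs[2]
    out$ess[k] <- ess_bulk(mat)
    out$rhat[k] <- if (single) NA_real_ else split_rhat(mat)
  }
  out
}

#' @export
summary.bvb_fit <- function(object, ...) {
  summarize_posterior(object, ...)
}

#' Combine chains into one draw matrix
#'
#' @param fit a [fit_bvar()] object.
#' @param scale see [summarize_posterior()].
#' @return matrix with one column per parameter, chains stacked.
#' @export
as_draws_matrix <- function(fit, scale = c("standardized", "original")) {
  scale <- match.arg(scale)
  chains <- fit$chains
  if (scale == "original") {
    chains <- lapply(chains, rescale_coefficients, codebook = fit$codebook)
  }
  do.call(rbind, chains)
}
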