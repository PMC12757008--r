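# Publication-style outputs: effect tables, periodic profiles, the moderated
# correlation at chosen exercise-identity values, the prior-sensitivity
# analysis and the parameter-recovery harness.

dynamics_params <- function() {
  c("sigma_L", "sigma_P", "tau_L", "tau_P", "alpha0", "alpha1",
    "beta_LL", "beta_LP", "beta_PL", "beta_PP")
}

#' Effect tables
#'
#' Splits a posterior summary (original covariate scale) into the three
#' blocks reported for this model family: mean-model effects on transformed
#' life satisfaction, mean-model effects on transformed physical activity,
#' and the variance/dynamics block (disturbance SDs, random-effect SDs,
#' correlation-link coefficients, transition matrix).  Each row carries a
#' `credible` flag: `TRUE` when the 95% credible interval excludes zero.
#'
#' @param summary data frame from [summarize_posterior()] (original scale).
#' @param codebook the dataset codebook (used to verify the row layout).
#' @return named list of data frames `ls_mean`, `pa_mean`, `dynamics`.
#' @export
effect_tables <- function(summary, codebook) {
  want <- c(paste0("delta_L.", codebook$columns),
            paste0("delta_P.", codebook$columns),
            dynamics_params())
  missing <- setdiff(want, summary$parameter)
  if (length(missing)) {
    stop("summary lacks parameter(s): ", paste(missing, collapse = ", "))
  }
  take <- function(keys) {
    tb <- summary[match(keys, summary$parameter), , drop = FALSE]
    tb$variable <- sub("^delta_[LP]\\.", "", tb$parameter)
    tb$credible <- tb$q2.5 > 0 | tb$q97.5 < 0
    rownames(tb) <- NULL
    tb[, c("variable", "mean", "sd", "q2.5", "q97.5", "ess", "rhat", "credible")]
  }
  list(ls_mean = take(paste0("delta_L.", codebook$columns)),
       pa_mean = take(paste0("delta_P.", codebook$columns)),
       dynamics = take(dynamics_params()))
}

#' Weekly and annual periodic profiles
#'
#' Extracts the weekday (Monday through Sunday, Monday fixed at 0 as the
#' reference) and month (January through December, January at 0) mean
#' profiles for one response from a posterior summary, and identifies the
#' level with the largest posterior-mean effect.
#'
#' @param summary data frame from [summarize_posterior()].
#' @param response `"L"` (life satisfaction) or `"P"` (physical activity).
#' @return list with data frames `weekday` and `month` (columns `level`,
#'   `mean`, `q2.5`, `q97.5`) carrying attributes `strongest` (level name of
#'   the maximal posterior mean among non-reference levels).
#' @export
periodic_profiles <- function(summary, response = c("L", "P")) {
  response <- match.arg(response)
  pull <- function(keys, labels) {
    idx <- match(keys, summary$parameter)
    if (anyNA(idx)) stop("summary lacks parameter(s): ",
                         paste(keys[is.na(idx)], collapse = ", "))
    df <- data.frame(level = labels,
                     mean = c(0, summary$mean[idx]),
                     q2.5 = c(0, summary$q2.5[idx]),
                     q97.5 = c(0, summary$q97.5[idx]),
                     stringsAsFactors = FALSE)
    attr(df, "strongest") <- labels[-1][which.max(summary$mean[idx])]
    df
  }
  wd_keys <- paste0("delta_", response, ".wd_",
                    c("tue", "wed", "thu", "fri", "sat", "sun"))
  mo_keys <- paste0("delta_", response, ".mon_",
                    c("feb", "mar", "apr", "may", "jun", "jul",
                      "aug", "sep", "oct", "nov", "dec"))
  list(weekday = pull(wd_keys, c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")),
       month = pull(mo_keys, c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                               "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")))
}

#' Moderated correlation at chosen exercise-identity values
#'
#' Evaluates the contemporaneous disturbance correlation
#' `tanh(alpha0 + alpha1 * exid_std)` draw by draw and summarizes it at each
#' requested standardized exercise-identity value.
#'
#' @param fit a [fit_bvar()] object, or a draw matrix with columns `alpha0`
#'   and `alpha1`.
#' @param exid_std numeric vector of standardized moderator values.
#' @return data frame `exid_std`, `rho` (posterior mean), `q2.5`, `q97.5`.
#' @export
correlation_at_exid <- function(fit, exid_std = c(-1, 0, 1)) {
  draws <- if (inherits(fit, "bvb_fit")) as_draws_matrix(fit) else as.matrix(fit)
  a0 <- draws[, "alpha0"]
  a1 <- draws[, "alpha1"]
  out <- lapply(exid_std, function(x) {
    r <- tanh(a0 + a1 * x)
    data.frame(exid_std = x, rho = mean(r),
               q2.5 = stats::quantile(r, 0.025, names = FALSE),
               q97.5 = stats::quantile(r, 0.975, names = FALSE))
  })
  do.call(rbind, out)
}

reported_mean_vector <- function(fit) {
  s <- summarize_posterior(fit, scale = "original", include_ranef = FALSE)
  stats::setNames(s$mean, s$parameter)
}

#' Prior-sensitivity analysis
#'
#' Refits the model with all half-normal prior SDs multiplied by each value
#' in `multipliers` (same data, same MCMC seed) and compares the resulting
#' posterior-mean vectors over all reported parameters (both mean blocks on
#' the original covariate scale plus the variance/dynamics block) against
#' the baseline multiplier 1: Pearson correlation and per-parameter maximum
#' absolute shift.  A refit whose maximum split-Rhat exceeds `rhat_max` is
#' reported as failed and its pair excluded.  Very small datasets (fewer
#' person-days than reported parameters) are flagged `prior_dominated`.
#'
#' @param dataset a [build_model_dataset()] object.
#' @param priors baseline [prior_config()].
#' @param multipliers prior-SD multipliers; must contain 1.
#' @param mcmc a [mcmc_config()].
#' @param rhat_max convergence gate for each refit.
#' @return list with `multipliers`, `correlations` (named by multiplier,
#'   vs the baseline), `max_abs_diff`, `failed`, `prior_dominated`, `means`
#'   (matrix of posterior-mean vectors).
#' @export
prior_sensitivity <- function(dataset, priors = prior_config(),
                              multipliers = c(0.5, 1, 2),
                              mcmc = mcmc_config(), rhat_max = 1.05) {
  if (!any(multipliers == 1)) stop("multipliers must include the baseline 1")
  labels <- make.unique(as.character(multipliers))
  means <- NULL
  failed <- stats::setNames(logical(length(multipliers)), labels)
  for (k in seq_along(multipliers)) {
    pr_k <- prior_config(sigma_scale = priors$sigma_scale,
                         tau_scale = priors$tau_scale,
                         coef_sd = priors$coef_sd,
                         multiplier = multipliers[k])
    fit_k <- fit_bvar(dataset, priors = pr_k, mcmc = mcmc)
    dg <- diagnose(fit_k, include_ranef = FALSE)
    failed[k] <- is.finite(dg$max_rhat) && dg$max_rhat > rhat_max
    mv <- reported_mean_vector(fit_k)
    means <- if (is.null(means)) matrix(mv, ncol = 1,
                                        dimnames = list(names(mv), NULL))
             else cbind(means, mv)
  }
  colnames(means) <- labels
  base <- labels[which(multipliers == 1)[1]]
  others <- setdiff(labels, base)
  correlations <- stats::setNames(rep(NA_real_, length(others)), others)
  max_abs_diff <- correlations
  for (o in others) {
    if (failed[base] || failed[o]) next
    correlations[o] <- stats::cor(means[, base], means[, o])
    max_abs_diff[o] <- max(abs(means[, base] - means[, o]))
  }
  list(multipliers = multipliers,
       correlations = correlations,
       max_abs_diff = max_abs_diff,
       failed = failed,
       prior_dominated = nrow(dataset$data) < nrow(means),
       means = means)
}

truth_vector <- function(params) {
  c(stats::setNames(params$delta_L, paste0("delta_L.", names(params$delta_L))),
    stats::setNames(params$delta_P, paste0("delta_P.", names(params$delta_P))),
    beta_LL = params$beta[1, 1], beta_LP = params$beta[1, 2],
    beta_PL = params$beta[2, 1], beta_PP = params$beta[2, 2],
    sigma_L = params$sigma_L, sigma_P = params$sigma_P,
    tau_L = params$tau_L, tau_P = params$tau_P,
    alpha0 = params$alpha0, alpha1 = params$alpha1)
}

#' Parameter-recovery study
#'
#' Simulates complete studies from a known truth, fits each one, and
#' summarizes recovery per parameter: bias and RMSE of the posterior mean
#' (original covariate scale) and empirical coverage of the 95% credible
#' interval.  Replicate-level failures are caught and recorded, not fatal.
#'
#' @param true_params a [bvb_params()] truth (original covariate scale).
#' @param n_persons participants per replicate.
#' @param n_replicates number of replicates (0 gives an empty report).
#' @param seed master seed; replicate r uses `seed + 1000 * r`.
#' @param n_bursts,burst_length design of each replicate.
#' @param mcmc a [mcmc_config()] for each replicate fit.
#' @param priors a [prior_config()].
#' @param mar_cfg missingness mechanism for the simulated studies.
#' @param observation `"exact"` (default) fits the latent model-scale values
#'   via [build_latent_dataset()], the parameter-recovery oracle;
#'   `"rendered"` fits the discretized measurements and so also reflects
#'   instrument attenuation.
#' @return object of class `bvb_recovery`: list with `table` (parameter,
#'   truth, mean_estimate, bias, rmse, coverage), `n_replicates`, `seeds`,
#'   `failures`.
#' @export
recovery_study <- function(true_params, n_persons = 150, n_replicates = 20,
                           seed = 1, n_bursts = 4, burst_length = 14,
                           mcmc = mcmc_config(chains = 2, warmup = 400,
                                              iter = 400),
                           priors = prior_config(),
                           mar_cfg = mar_config(),
                           observation = c("exact", "rendered")) {
  observation <- match.arg(observation)
  truth <- truth_vector(true_params)
  seeds <- seed + 1000L * seq_len(n_replicates)
  est <- matrix(NA_real_, length(truth), n_replicates,
                dimnames = list(names(truth), NULL))
  cover <- est
  failures <- character(0)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      study <- simulate_study(n_persons, params = true_params,
                              seed = seeds[r], n_bursts = n_bursts,
                              burst_length = burst_length, mar_cfg = mar_cfg)
      ds <- if (observation == "exact") build_latent_dataset(study)
            else build_model_dataset(study$daily, study$participants,
                                     study$calendar)
      mc <- mcmc
      mc$seed <- seeds[r]
      fit <- fit_bvar(ds, priors = priors, mcmc = mc)
      summarize_posterior(fit, scale = "original", include_ranef = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r, conditionMessage(res)))
      next
    }
    idx <- match(names(truth), res$parameter)
    est[, r] <- res$mean[idx]
    cover[, r] <- truth >= res$q2.5[idx] & truth <= res$q97.5[idx]
  }
  done <- colSums(is.na(est)) == 0
  tab <- data.frame(
    parameter = names(truth),
    truth = unname(truth),
    mean_estimate = rowMeans(est[, done, drop = FALSE]),
    bias = rowMeans(est[, done, drop = FALSE]) - unname(truth),
    rmse = sqrt(rowMeans((est[, done, drop = FALSE] - truth)^2)),
    coverage = rowMeans(cover[, done, drop = FALSE]),
    stringsAsFactors = FALSE
  )
  if (!any(done)) tab <- tab[0, ]
  out <- list(table = tab, n_replicates = sum(done), seeds = seeds,
              failures = failures)
  class(out) <- "bvb_recovery"
  out
}

#' @export
print.bvb_recovery <- function(x, ...) {
  cat("<bvb_recovery> ", x$n_replicates, " completed replicates\n", sep = "")
  if (nrow(x$table)) {
    key <- c("beta_LL", "beta_PP", "alpha0", "alpha1", "sigma_L", "sigma_P")
    print(x$table[x$table$parameter %in% key, ], row.names = FALSE, digits = 3)
  }
  if (length(x$failures)) cat("failures:\n", paste(" -", x$failures, "\n"))
  invisible(x)
}

#' Write / read effect tables as CSV
#'
#' Numeric fields are serialized with 17 significant digits so that writing
#' and re-reading reproduces every value exactly.
#'
#' @param tables list from [effect_tables()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_effect_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    num <- vapply(tb, is.numeric, logical(1))
    tb[num] <- lapply(tb[num], function(v) sprintf("%.17g", v))
    p <- file.path(dir, paste0("effects_", nm, ".csv"))
    utils::write.csv(tb, p, row.names = FALSE, quote = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_effect_tables
#' @export
read_effect_tables <- function(dir) {
  files <- list.files(dir, pattern = "^effects_.*\\.csv$", full.names = TRUE)
  out <- list()
  for (p in files) {
    tb <- utils::read.csv(p, stringsAsFactors = FALSE)
    for (cc in c("mean", "sd", "q2.5", "q97.5", "ess", "rhat")) {
      if (cc %in% names(tb)) tb[[cc]] <- as.numeric(tb[[cc]])
    }
    out[[sub("^effects_(.*)\\.csv$", "\\1", basename(p))]] <- tb
  }
  out
}
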