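#' Priors for the log-log power-law regression
#'
#' The power law `y = c * x^k` is fitted on log axes as
#' `log y = log c + k log x` with independent normal priors on `log c` and
#' `k` and an inverse-gamma prior on the residual variance `sigma^2`. The
#' defaults are weakly informative — Normal(0, 10^2) on both coefficients
#' and Inverse-Gamma(0.01, 0.01) on the variance — so with a dozen or more
#' observations the likelihood dominates.
#'
#' @param logc_mean,logc_sd Normal prior mean and sd for the log intercept
#'   (in the fit's log base units).
#' @param k_mean,k_sd Normal prior mean and sd for the exponent `k`
#'   (dimensionless).
#' @param sigma2_shape,sigma2_rate Inverse-gamma shape and rate for the
#'   residual variance.
#' @return An object of class `power_law_priors`.
#' @export
power_law_priors <- function(logc_mean = 0, logc_sd = 10,
                             k_mean = 0, k_sd = 10,
                             sigma2_shape = 0.01, sigma2_rate = 0.01) {
  if (logc_sd <= 0 || k_sd <= 0)
    stop("prior standard deviations must be positive", call. = FALSE)
  if (sigma2_shape <= 0 || sigma2_rate <= 0)
    stop("variance-prior hyperparameters must be positive for a proper prior",
         call. = FALSE)
  structure(list(logc_mean = logc_mean, logc_sd = logc_sd,
                 k_mean = k_mean, k_sd = k_sd,
                 sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate),
            class = "power_law_priors")
}

#' MCMC settings for the Gibbs sampler
#'
#' Defaults (3 chains of 20,000 iterations, 5,000 burn-in, no thinning)
#' are deliberately generous: the conjugate Gibbs updates mix quickly and
#' a fit at n = 15 costs a fraction of a second.
#'
#' @param chains Number of chains (>= 2 so convergence can be assessed).
#' @param iterations Iterations per chain, including burn-in.
#' @param burn_in Burn-in iterations discarded per chain.
#' @param thin Thinning interval (1 keeps every draw).
#' @param seed Integer random seed; identical seed and settings give
#'   identical draws.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, iterations = 20000, burn_in = 5000,
                        thin = 1, seed = 1) {
  if (chains < 2) stop("at least 2 chains are required for diagnostics",
                       call. = FALSE)
  if (burn_in < 0 || iterations <= burn_in)
    stop("need iterations > burn_in >= 0", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Fit the predator-prey power law by Bayesian regression
#'
#' Fits `log y = log c + k log x` with Gaussian residuals by conjugate
#' Gibbs sampling: the coefficient vector is drawn from its exact
#' multivariate-normal full conditional and the residual variance from its
#' exact inverse-gamma full conditional. Posterior summaries (mean, median
#' and central 95% credible interval) are computed from the post-burn-in,
#' thinned draws of all chains, with split-chain potential scale reduction
#' and effective sample size per parameter.
#'
#' @param x Prey biomass densities (kg/km^2), strictly positive.
#' @param y Predator biomass densities (kg/km^2), strictly positive.
#' @param priors A [power_law_priors()] object.
#' @param mcmc An [mcmc_config()] object.
#' @param log_base Base of the logarithm used on both axes (default 10;
#'   `k` is invariant to the base, `log c` is reported in this base).
#' @param response Label for the response series (`"total"`, `"tiger"`,
#'   `"leopard"`, ...).
#' @return An object of class `power_law_fit` with elements `summary`
#'   (data frame over `logc`, `k`, `sigma`), `draws` (matrix with chain
#'   index), `rhat`, `ess`, `n`, `log_base`, `response`, and the log-scale
#'   data used.
#'
#' @examples
#' x <- c(500, 1000, 2000, 4000, 8000)
#' y <- 10^(1 + 2 * log10(x))       # exact line with k = 2
#' fit <- fit_power_law(x, y, mcmc = mcmc_config(iterations = 4000,
#'                                               burn_in = 1000))
#' coef(fit)
#' @export
fit_power_law <- function(x, y, priors = power_law_priors(),
                          mcmc = mcmc_config(), log_base = 10,
                          response = "total") {
  stopifnot(inherits(priors, "power_law_priors"),
            inherits(mcmc, "mcmc_config"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("biomass densities must be strictly positive for a log-scale fit",
         call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)

  lx <- log(x, base = log_base)
  ly <- log(y, base = log_base)
  X <- cbind(1, lx)
  ols <- stats::lm.fit(X, ly)
  s2_ols <- max(sum(ols$residuals^2) / max(n - 2, 1), 1e-8)

  set.seed(mcmc$seed)
  prior_mean <- c(priors$logc_mean, priors$k_mean)
  prior_sd <- c(priors$logc_sd, priors$k_sd)
  draws <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    beta_init <- ols$coefficients + rnorm(2, 0, 2 * sqrt(s2_ols))
    sigma2_init <- s2_ols * exp(rnorm(1, 0, 1))
    d <- .gibbs_conjugate_lm(ly, X, prior_mean, prior_sd,
                             priors$sigma2_shape, priors$sigma2_rate,
                             mcmc$iterations, mcmc$burn_in, mcmc$thin,
                             beta_init, sigma2_init)
    colnames(d) <- c("logc", "k", "sigma")
    draws[[ch]] <- d
  }

  pars <- c("logc", "k", "sigma")
  rhat <- vapply(pars, function(p) .split_rhat(lapply(draws, `[`, , p)),
                 numeric(1))
  ess <- vapply(pars, function(p) .ess(lapply(draws, `[`, , p)), numeric(1))
  all_draws <- do.call(rbind, draws)
  summ <- data.frame(
    parameter = pars,
    mean = colMeans(all_draws),
    median = apply(all_draws, 2, median),
    lower_95 = apply(all_draws, 2, quantile, probs = 0.025),
    upper_95 = apply(all_draws, 2, quantile, probs = 0.975),
    rhat = rhat, ess = ess,
    row.names = NULL, stringsAsFactors = FALSE
  )
  converged <- all(is.finite(rhat)) && all(rhat < 1.01)
  if (!converged)
    warning(sprintf(
      "power-law fit ('%s') may not have converged: max Rhat = %.3f",
      response, max(rhat)), call. = FALSE)

  fit <- structure(list(
    response = response, n = n, log_base = log_base,
    summary = summ,
    draws = cbind(chain = rep(seq_len(mcmc$chains),
                              each = nrow(draws[[1]])), all_draws),
    rhat = rhat, ess = ess, converged = converged,
    log_x = lx, log_y = ly,
    priors = priors, mcmc = mcmc
  ), class = "power_law_fit")
  fit
}

#' @export
coef.power_law_fit <- function(object, ...) {
  setNames(object$summary$mean, object$summary$parameter)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Bayesian power-law fit (response: %s, n = %d, log base %g)\n",
              x$response, x$n, x$log_base))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s mean %8.4f  median %8.4f  95%% CI [%.4f, %.4f]  Rhat %.3f  ESS %.0f\n",
                s$parameter[i], s$mean[i], s$median[i], s$lower_95[i],
                s$upper_95[i], s$rhat[i], s$ess[i]))
  }
  if (!x$converged) cat("  WARNING: convergence diagnostics exceed threshold\n")
  invisible(x)
}

#' Fit total, tiger-only and leopard-only power laws
#'
#' Runs the log-log regression three times against the same prey biomass
#' series: total predator biomass (tiger + leopard), tiger biomass alone,
#' and leopard biomass alone. Records lacking a leopard biomass are kept
#' for the tiger-only fit but dropped, with a warning, from the total and
#' leopard fits; records with zero biomass on a log-scale axis are dropped
#' with a warning rather than floored.
#'
#' @param biomass A `biomass_table` from [densities_to_biomass()].
#' @param priors A [power_law_priors()] object, shared by the three fits.
#' @param mcmc An [mcmc_config()] object; fits use `seed`, `seed + 1`,
#'   `seed + 2` so the three posteriors are independent but reproducible.
#' @return A list of class `power_law_fits` with elements `total`, `tiger`
#'   and `leopard` (the latter two `NULL` when no usable records exist).
#' @export
fit_all_three <- function(biomass, priors = power_law_priors(),
                          mcmc = mcmc_config()) {
  stopifnot(is.data.frame(biomass))
  need <- c("tiger_biomass", "leopard_biomass", "predator_biomass",
            "prey_biomass")
  if (!all(need %in% names(biomass)))
    stop("`biomass` must be a biomass table (see densities_to_biomass)",
         call. = FALSE)
  # keep the total consistent with its parts (NA leopard => NA total)
  biomass$predator_biomass <- biomass$tiger_biomass + biomass$leopard_biomass

  drop_nonpos <- function(df, col, label) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] <= 0 | df$prey_biomass <= 0))
    if (length(bad) > 0) {
      warning(sprintf("excluding %d record(s) with zero %s or prey biomass from the %s fit",
                      length(bad), label, label), call. = FALSE)
      df <- df[-bad, , drop = FALSE]
    }
    df[!is.na(df[[col]]), , drop = FALSE]
  }

  n_leopard_na <- sum(is.na(biomass$leopard_biomass))
  if (n_leopard_na > 0)
    warning(sprintf("%d record(s) lack leopard biomass; excluded from the total and leopard fits",
                    n_leopard_na), call. = FALSE)

  mc <- function(offset) mcmc_config(mcmc$chains, mcmc$iterations,
                                     mcmc$burn_in, mcmc$thin,
                                     mcmc$seed + offset)
  tot <- drop_nonpos(biomass, "predator_biomass", "total predator")
  tig <- drop_nonpos(biomass, "tiger_biomass", "tiger")
  leo <- drop_nonpos(biomass, "leopard_biomass", "leopard")

  fits <- list(
    total = if (nrow(tot) >= 3)
      fit_power_law(tot$prey_biomass, tot$predator_biomass, priors, mc(0),
                    response = "total") else NULL,
    tiger = if (nrow(tig) >= 3)
      fit_power_law(tig$prey_biomass, tig$tiger_biomass, priors, mc(1),
                    response = "tiger") else NULL,
    leopard = if (nrow(leo) >= 3)
      fit_power_law(leo$prey_biomass, leo$leopard_biomass, priors, mc(2),
                    response = "leopard") else NULL
  )
  class(fits) <- "power_law_fits"
  fits
}

#' @export
print.power_law_fits <- function(x, ...) {
  for (nm in names(x)) {
    if (is.null(x[[nm]])) cat(sprintf("[%s] not fitted\n", nm))
    else print(x[[nm]])
  }
  invisible(x)
}

#' Simulate a power-law dataset and check parameter recovery
#'
#' Generates `n` observations with `log y = true_logc + true_k * log x`
#' plus Gaussian noise over a stated prey-biomass range, fits the model,
#' and reports truth, estimate, 95% credible interval and whether the
#' interval covers the truth — the standard simulate-then-recover check
#' run before trusting a fit on real data.
#'
#' @param true_logc,true_k,true_sigma Generating parameters (log base 10).
#' @param n Number of observations (>= 3).
#' @param seed Random seed for the simulated data.
#' @param priors,mcmc Passed to [fit_power_law()].
#' @param x_range Prey biomass range (kg/km^2) sampled uniformly on the
#'   log scale.
#' @return A list of class `recovery_report` with the truth, the fit, and
#'   a per-parameter comparison table.
#' @export
simulate_and_recover <- function(true_logc, true_k, true_sigma, n = 15,
                                 seed = 1, priors = power_law_priors(),
                                 mcmc = mcmc_config(),
                                 x_range = c(100, 5000)) {
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (true_sigma < 0) stop("true_sigma must be >= 0", call. = FALSE)
  set.seed(seed)
  lx <- runif(n, log10(x_range[1]), log10(x_range[2]))
  ly <- true_logc + true_k * lx + rnorm(n, 0, true_sigma)
  fit <- fit_power_law(10^lx, 10^ly, priors = priors, mcmc = mcmc)
  truth <- c(logc = true_logc, k = true_k, sigma = true_sigma)
  s <- fit$summary[fit$summary$parameter %in% c("logc", "k"), ]
  tab <- data.frame(
    parameter = s$parameter,
    truth = truth[s$parameter],
    estimate = s$mean,
    lower_95 = s$lower_95,
    upper_95 = s$upper_95,
    covered = truth[s$parameter] >= s$lower_95 & truth[s$parameter] <= s$upper_95,
    row.names = NULL
  )
  structure(list(truth = truth, fit = fit, table = tab, seed = seed, n = n),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Simulate-and-recover report (n = %d, seed = %d)\n", x$n, x$seed))
  print(x$table, digits = 4)
  invisible(x)
}

#' Predator fold-change implied by the fitted exponent
#'
#' A power law `y = c x^k` implies that an `prey_fold`-fold increase in
#' prey biomass multiplies predator biomass by `prey_fold^k`. With the
#' exponent near 0.71 a fivefold prey increase yields roughly a threefold
#' predator increase — the hallmark of an increasingly bottom-heavy
#' biomass pyramid (k < 1).
#'
#' @param fit A `power_law_fit`, or a plain numeric exponent.
#' @param prey_fold Fold increase in prey biomass (default 5).
#' @return The implied multiplicative change in predator biomass.
#' @export
predicted_fold_change <- function(fit, prey_fold = 5) {
  k <- if (inherits(fit, "power_law_fit")) coef(fit)[["k"]] else as.numeric(fit)
  if (prey_fold <= 0) stop("prey_fold must be positive", call. = FALSE)
  prey_fold^k
}

# ---- convergence diagnostics -------------------------------------------

# split-chain potential scale reduction (each chain halved)
.split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    m <- length(ch) %/% 2
    halves <- c(halves, list(ch[1:m]), list(ch[(m + 1):(2 * m)]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via Geyer's initial positive sequence, per chain
.ess <- function(chains) {
  ess_one <- function(v) {
    n <- length(v)
    if (var(v) <= 0) return(n)
    lag_max <- min(n - 1, 200)
    rho <- stats::acf(v, lag.max = lag_max, plot = FALSE)$acf[-1]
    tau <- 1
    t <- 1
    while (t + 1 <= length(rho)) {
      pair <- rho[t] + rho[t + 1]
      if (pair < 0) break
      tau <- tau + 2 * pair
      t <- t + 2
    }
    n / tau
  }
  sum(vapply(chains, ess_one, numeric(1)))
}
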