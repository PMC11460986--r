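# fixed log-normal fixture used by several fits
.fixture_xy <- function(seed = 42, n = 15, logc = -1.8, k = 0.75,
                        sigma = 0.3) {
  set.seed(seed)
  lx <- runif(n, 2, log10(5000))
  ly <- logc + k * lx + rnorm(n, 0, sigma)
  list(x = 10^lx, y = 10^ly)
}

test_that("Gibbs conditionals match the closed-form conjugate moments", {
  d <- .fixture_xy(seed = 1)
  lx <- log10(d$x); ly <- log10(d$y)
  X <- cbind(1, lx)

  # (i) pin sigma^2 with a concentrated inverse-gamma prior; the beta draws
  # must then follow the exact normal full conditional
  s2_0 <- 0.04
  pr <- power_law_priors(sigma2_shape = 1e8, sigma2_rate = 1e8 * s2_0)
  fit <- fit_power_law(d$x, d$y, priors = pr, mcmc = fast_mcmc(2))
  P <- diag(1 / c(10, 10)^2)
  V <- solve(crossprod(X) / s2_0 + P)
  m <- V %*% (crossprod(X, ly) / s2_0)
  draws <- fit$draws[, c("logc", "k")]
  mcse <- sqrt(diag(V) / nrow(draws)) * 3  # generous: draws are correlated
  expect_lt(abs(mean(draws[, "logc"]) - m[1]), 10 * mcse[1])
  expect_lt(abs(mean(draws[, "k"]) - m[2]), 10 * mcse[2])
  expect_equal(unname(apply(draws, 2, sd)), unname(sqrt(diag(V))),
               tolerance = 0.05)

  # (ii) pin beta with a near-degenerate prior; sigma^2 must then follow the
  # inverse-gamma full conditional at that beta
  beta0 <- c(-1.5, 0.7)
  pr2 <- power_law_priors(logc_mean = beta0[1], logc_sd = 1e-8,
                          k_mean = beta0[2], k_sd = 1e-8,
                          sigma2_shape = 0.01, sigma2_rate = 0.01)
  fit2 <- fit_power_law(d$x, d$y, priors = pr2, mcmc = fast_mcmc(3))
  rss <- sum((ly - X %*% beta0)^2)
  shape <- 0.01 + length(ly) / 2
  rate <- 0.01 + rss / 2
  expect_equal(mean(fit2$draws[, "sigma"]^2), rate / (shape - 1),
               tolerance = 0.05)
})

test_that("posterior means agree with the OLS oracle under vague priors", {
  d <- .fixture_xy(seed = 42)
  fit <- fit_power_law(d$x, d$y)  # default 3 x 20000 draws
  ols <- ols_loglog(d$x, d$y)
  expect_lt(abs(coef(fit)[["k"]] - ols[2]), 0.01)
  expect_lt(abs(coef(fit)[["logc"]] - ols[1]), 0.01)
  expect_true(all(fit$rhat < 1.01))
  expect_true(all(fit$summary$lower_95 < fit$summary$upper_95))
})

test_that("noiseless data concentrate the posterior on the generating line", {
  lx <- seq(1, 4, length.out = 8)
  fit <- fit_power_law(10^lx, 10^(1 + 2 * lx), mcmc = fast_mcmc(4))
  expect_equal(coef(fit)[["k"]], 2, tolerance = 1e-3)
  expect_equal(coef(fit)[["logc"]], 1, tolerance = 1e-2)
})

test_that("the exponent is invariant to the logarithm base", {
  d <- .fixture_xy(seed = 7)
  f10 <- fit_power_law(d$x, d$y, mcmc = fast_mcmc(7), log_base = 10)
  fe <- fit_power_law(d$x, d$y, mcmc = fast_mcmc(7), log_base = exp(1))
  expect_equal(coef(f10)[["k"]], coef(fe)[["k"]], tolerance = 0.01)
  # intercepts are base-specific: logc_e = logc_10 * ln(10)
  expect_equal(coef(fe)[["logc"]], coef(f10)[["logc"]] * log(10),
               tolerance = 0.05)
})

test_that("a tight prior on k dominates the likelihood", {
  d <- .fixture_xy(seed = 8)
  pr <- power_law_priors(k_mean = 3, k_sd = 1e-3)
  fit <- fit_power_law(d$x, d$y, priors = pr, mcmc = fast_mcmc(8))
  expect_equal(coef(fit)[["k"]], 3, tolerance = 0.01)
})

test_that("credible intervals shrink as the sample grows", {
  width <- function(n, seed) {
    rec <- simulate_and_recover(-1.8, 0.75, 0.3, n = n, seed = seed,
                                mcmc = fast_mcmc(seed))
    s <- rec$fit$summary
    s$upper_95[s$parameter == "k"] - s$lower_95[s$parameter == "k"]
  }
  w_small <- vapply(1:5, function(s) width(10, s), numeric(1))
  w_large <- vapply(1:5, function(s) width(80, s), numeric(1))
  expect_lt(mean(w_large), mean(w_small))
})

test_that("fit_all_three respects symmetry and handles degenerate responses", {
  # tiger and leopard biomass equal on every record
  set.seed(21)
  lx <- runif(12, 2, 3.7)
  tot <- 10^(-1.8 + 0.75 * lx + rnorm(12, 0, 0.2))
  bio <- biomass_table_from(tiger = tot / 2, leopard = tot / 2, prey = 10^lx)
  fits <- fit_all_three(bio, mcmc = fast_mcmc(21))
  expect_equal(coef(fits$tiger)[["k"]], coef(fits$leopard)[["k"]],
               tolerance = 0.02)
  expect_equal(coef(fits$total)[["k"]], coef(fits$tiger)[["k"]],
               tolerance = 0.02)

  # constant leopard biomass: slope indistinguishable from the flat oracle
  bio2 <- biomass_table_from(tiger = tot / 2, leopard = rep(2, 12),
                             prey = 10^lx)
  fits2 <- fit_all_three(bio2, mcmc = fast_mcmc(22))
  expect_equal(coef(fits2$leopard)[["k"]], 0, tolerance = 0.01)

  # leopard-missing records are excluded with a warning
  bio3 <- bio
  bio3$leopard_biomass[1:2] <- NA
  expect_warning(fits3 <- fit_all_three(bio3, mcmc = fast_mcmc(23)),
                 "lack leopard biomass")
  expect_equal(fits3$total$n, 10)
  expect_equal(fits3$tiger$n, 12)
})

test_that("simulate_and_recover is deterministic and exact without noise", {
  r1 <- simulate_and_recover(-1.8, 0.75, 0.3, n = 15, seed = 99,
                             mcmc = fast_mcmc(99))
  r2 <- simulate_and_recover(-1.8, 0.75, 0.3, n = 15, seed = 99,
                             mcmc = fast_mcmc(99))
  expect_identical(r1$table, r2$table)
  expect_identical(r1$fit$summary, r2$fit$summary)

  r0 <- simulate_and_recover(-1.8, 0.75, 0, n = 15, seed = 100,
                             mcmc = fast_mcmc(100))
  expect_equal(r0$table$estimate[r0$table$parameter == "k"], 0.75,
               tolerance = 1e-3)
  expect_true(all(r0$table$covered))
})

test_that("input validation rejects unusable data", {
  expect_error(fit_power_law(c(1, 2, 3), c(1, -2, 3)), "positive")
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_power_law(c(1, 2, NA), c(1, 2, 3)), "NA")
  expect_error(power_law_priors(k_sd = 0), "positive")
  expect_error(mcmc_config(chains = 1), "2 chains")
  expect_error(mcmc_config(iterations = 100, burn_in = 100), "burn_in")
})
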