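test_that("the multiplicative decomposition identity holds exactly", {
  bio <- make_biomass_fixture(seed = 2)
  dec <- decompose_predators(bio)
  expect_equal(dec$log_tiger + dec$log_ratio, log10(bio$predator_biomass),
               tolerance = 1e-12)

  # equal biomass doubles the total: the leopard component is log 2
  b2 <- biomass_table_from(tiger = c(4, 9, 2, 5), leopard = c(4, 9, 2, 5),
                           prey = c(100, 900, 50, 400))
  expect_equal(decompose_predators(b2)$log_ratio, rep(log10(2), 4))

  # no leopards: the leopard component vanishes
  b0 <- biomass_table_from(tiger = c(4, 9, 2, 5), leopard = 0,
                           prey = c(100, 900, 50, 400))
  expect_equal(decompose_predators(b0)$log_ratio, rep(0, 4))

  # worked example
  b1 <- biomass_table_from(tiger = 7.308, leopard = 2.1, prey = c(5000))
  d1 <- decompose_predators(rbind(b1, biomass_table_from(3, 1, 100)))
  expect_equal(d1$log_tiger[1], 0.8638, tolerance = 1e-4)
  expect_equal(d1$log_ratio[1], 0.1097, tolerance = 1e-4)
  expect_equal(d1$log_tiger[1] + d1$log_ratio[1], log10(9.408),
               tolerance = 1e-12)

  # zero tiger biomass has no defined log: rejected, naming the record
  bt <- biomass_table_from(tiger = c(0, 2), leopard = c(1, 1),
                           prey = c(100, 200))
  expect_error(decompose_predators(bt), "P01")

  # missing leopard records are excluded with a warning
  bna <- make_biomass_fixture(seed = 2)
  bna$leopard_biomass[3] <- NA
  expect_warning(dna <- decompose_predators(bna), "excluded")
  expect_equal(nrow(dna), 14)
})

test_that("canonical correlation equals the multiple correlation (q = 1)", {
  for (seed in c(1, 12, 33, 54, 75)) {
    bio <- make_biomass_fixture(seed = seed)
    dec <- decompose_predators(bio)
    cca <- fit_cca(dec)
    r2 <- summary(lm(log_prey ~ log_tiger + log_ratio, data = dec))$r.squared
    expect_equal(cca$rho, sqrt(r2), tolerance = 1e-10)
    expect_gte(cca$rho, 0)
    expect_lte(cca$rho, 1)

    # independent cross-check against the reference CCA implementation
    cc <- cancor(cbind(dec$log_tiger, dec$log_ratio), dec$log_prey)
    expect_equal(cca$rho, unname(cc$cor[1]), tolerance = 1e-10)
    ratio <- unname(cca$alpha_unit / cc$xcoef[, 1])
    expect_equal(ratio[1], ratio[2], tolerance = 1e-8)  # same direction
  }
})

test_that("rho is invariant to affine rescaling and detects degeneracy", {
  bio <- make_biomass_fixture(seed = 6)
  dec <- decompose_predators(bio)
  cca <- fit_cca(dec)

  dec2 <- dec
  dec2$log_tiger <- 2.5 * dec2$log_tiger + 1
  dec2$log_ratio <- 0.3 * dec2$log_ratio - 4
  dec2$log_prey <- 1.7 * dec2$log_prey + 0.2
  expect_equal(fit_cca(dec2)$rho, cca$rho, tolerance = 1e-10)

  # exact linear combination on the prey side gives rho = 1
  dec3 <- dec
  dec3$log_prey <- 0.4 * dec3$log_tiger + 1.3 * dec3$log_ratio + 2
  expect_equal(fit_cca(dec3)$rho, 1, tolerance = 1e-10)

  # collinear predator components are rejected
  t_vals <- 10^seq(0.1, 1, length.out = 6)
  bc <- biomass_table_from(tiger = t_vals,
                           leopard = t_vals * (t_vals^2 - 1),
                           prey = 10^runif(6, 2, 3.5))
  expect_error(fit_cca(decompose_predators(bc)), "collinear")

  # constant leopard share: zero variance in the leopard component
  bzv <- biomass_table_from(tiger = c(2, 4, 8, 16, 32),
                            leopard = c(2, 4, 8, 16, 32),
                            prey = 10^seq(2, 3.6, length.out = 5))
  expect_error(fit_cca(decompose_predators(bzv)), "zero variance")

  expect_error(fit_cca(decompose_predators(
    biomass_table_from(tiger = c(1, 2, 3), leopard = c(0.5, 1, 2),
                       prey = c(100, 200, 300)))), "more than 3")
})

test_that("the Wilks-Bartlett chain follows its closed form", {
  w <- wilks_test(rho = 0.5, n = 20)
  expect_equal(unname(w$estimate[["Wilks lambda"]]), 0.75)
  expect_equal(unname(w$statistic), -17 * log(0.75), tolerance = 1e-10)
  expect_equal(unname(w$statistic), 4.890, tolerance = 1e-3)
  expect_equal(unname(w$parameter), 2)
  expect_equal(w$p.value, 0.0867, tolerance = 1e-4)

  w0 <- wilks_test(rho = 0, n = 15)
  expect_equal(unname(w0$statistic), 0)
  expect_equal(w0$p.value, 1)

  w1 <- wilks_test(rho = 1, n = 15)
  expect_true(is.infinite(w1$statistic))
  expect_equal(w1$p.value, 0)

  expect_error(wilks_test(rho = 0.5, n = 4), "n > p \\+ q \\+ 1")
  expect_error(wilks_test(rho = 1.2, n = 15), "rho")
})

test_that("the scaled relationship matches the regression-correlation identity", {
  bio <- make_biomass_fixture(seed = 13)
  dec <- decompose_predators(bio)
  cca <- fit_cca(dec)
  fit <- fit_power_law(bio$prey_biomass, bio$predator_biomass,
                       mcmc = fast_mcmc(13))
  rel <- scaled_relationship(cca, fit)
  k <- coef(fit)[["k"]]
  expect_equal(rel$slope, cca$rho * k)

  # predator variate spread matches the prey variate k * log x
  P <- rel$alpha[["alpha1"]] * dec$log_tiger +
    rel$alpha[["alpha2"]] * dec$log_ratio
  expect_equal(sd(P), abs(k) * sd(dec$log_prey), tolerance = 1e-10)

  # rho = beta * sd(x) / sd(y) for the regression between the variates
  Q <- k * dec$log_prey
  beta <- cov(P, Q) / var(Q)
  expect_equal(cca$rho, beta * sd(Q) / sd(P), tolerance = 1e-10)

  # the centering constant puts the relation through the sample means
  expect_equal(mean(P), rel$slope * mean(dec$log_prey) + rel$intercept,
               tolerance = 1e-10)

  # a fit on different observations is refused
  fit2 <- fit_power_law(bio$prey_biomass[-1], bio$predator_biomass[-1],
                        mcmc = fast_mcmc(14))
  expect_error(scaled_relationship(cca, fit2), "same observations")
})

test_that("margins implement rho*k/alpha and anchor through the means", {
  bio <- make_biomass_fixture(seed = 17)
  dec <- decompose_predators(bio)
  cca <- fit_cca(dec)
  fit <- fit_power_law(bio$prey_biomass, bio$predator_biomass,
                       mcmc = fast_mcmc(17))
  rel <- scaled_relationship(cca, fit)
  m <- margins(cca, fit)
  expect_equal(m$tiger_margin_slope, rel$slope / rel$alpha[["alpha1"]])
  expect_equal(m$leopard_margin_slope, rel$slope / rel$alpha[["alpha2"]])

  # the tiger margin line is the relation with the leopard component zeroed
  x0 <- 1000
  lhs <- rel$alpha[["alpha1"]] *
    log10(predict_margin(m, x0, "tiger"))
  expect_equal(lhs, rel$slope * log10(x0) + rel$intercept, tolerance = 1e-10)

  # the leopard reference shifts the intercept, not the slope
  m5 <- margins(cca, fit, tiger_reference = 5)
  expect_equal(m5$leopard_margin_slope, m$leopard_margin_slope)
  expect_false(isTRUE(all.equal(m5$leopard_margin_intercept,
                                m$leopard_margin_intercept)))
  expect_error(margins(cca, fit, tiger_reference = 0), "positive")
})

test_that("the competition gap compares margin and regression on a grid", {
  bio <- make_biomass_fixture(seed = 19)
  fits <- fit_all_three(bio, mcmc = fast_mcmc(19))
  cca <- fit_cca(decompose_predators(bio))
  m <- margins(cca, fits$total)
  grid <- 10^seq(2, log10(5000), length.out = 25)
  gap <- competition_gap(m, fits$tiger, grid)
  expect_equal(nrow(gap), 25)
  expect_true(all(gap$margin > 0))
  expect_true(all(gap$regression > 0))
  expect_equal(gap$gap, gap$margin - gap$regression)
  expect_identical(attr(gap, "species"), "tiger")
  expect_equal(attr(gap, "slope_gap"),
               m$tiger_margin_slope - coef(fits$tiger)[["k"]])

  # points beyond the observed prey range are flagged
  inner <- 10^seq(m$x_range[1], m$x_range[2], length.out = 5)
  wide <- competition_gap(m, fits$tiger, c(1, inner, 1e6))
  expect_true(wide$extrapolated[1])
  expect_true(wide$extrapolated[nrow(wide)])
  expect_false(any(wide$extrapolated[2:6]))

  expect_error(competition_gap(m, fits$tiger, numeric(0)), "empty")
  expect_error(competition_gap(m, fits$tiger, c(-1, 10)), "positive")
})
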