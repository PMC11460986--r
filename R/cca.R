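#' Multiplicative decomposition of total predator biomass
#'
#' Splits the log of total predator biomass exactly into a tiger term and
#' a leopard term:
#' `log(T+L) = log T + log((T+L)/T)`.
#' The second term — the log of the relative increase in predator biomass
#' when leopards are counted on top of tigers — is the leopard component
#' after accounting for tiger predation: it is 0 when there are no
#' leopards and `log 2` when the two species hold equal biomass.
#'
#' @param biomass A `biomass_table`; every record entering the
#'   decomposition must have strictly positive tiger and prey biomass
#'   (records with zero tiger biomass have no defined log and are rejected
#'   with an error naming them; records lacking leopard biomass are
#'   excluded with a warning).
#' @param log_base Logarithm base (default 10).
#' @return A `data.frame` of class `predator_decomposition` with columns
#'   `park`, `year`, `log_tiger`, `log_ratio`, `log_prey`. The identity
#'   `log_tiger + log_ratio == log(T+L)` holds exactly per record.
#' @export
decompose_predators <- function(biomass, log_base = 10) {
  stopifnot(is.data.frame(biomass))
  need <- c("tiger_biomass", "leopard_biomass", "prey_biomass")
  if (!all(need %in% names(biomass)))
    stop("`biomass` must be a biomass table (see densities_to_biomass)",
         call. = FALSE)
  x <- biomass
  drop <- is.na(x$leopard_biomass)
  if (any(drop)) {
    warning(sprintf("%d record(s) without leopard biomass excluded from the joint decomposition",
                    sum(drop)), call. = FALSE)
    x <- x[!drop, , drop = FALSE]
  }
  bad_t <- which(x$tiger_biomass <= 0)
  if (length(bad_t) > 0)
    stop(sprintf("tiger biomass is zero for record (%s, %s): log T is undefined, so the record cannot enter the joint analysis",
                 x$park[bad_t[1]], x$year[bad_t[1]]), call. = FALSE)
  bad_x <- which(x$prey_biomass <= 0)
  if (length(bad_x) > 0)
    stop(sprintf("prey biomass is zero for record (%s, %s): log x is undefined",
                 x$park[bad_x[1]], x$year[bad_x[1]]), call. = FALSE)
  if (any(x$leopard_biomass < 0))
    stop("leopard biomass must be >= 0", call. = FALSE)

  out <- data.frame(
    park = x$park, year = x$year,
    log_tiger = log(x$tiger_biomass, base = log_base),
    log_ratio = log((x$tiger_biomass + x$leopard_biomass) / x$tiger_biomass,
                    base = log_base),
    log_prey = log(x$prey_biomass, base = log_base),
    stringsAsFactors = FALSE
  )
  attr(out, "log_base") <- log_base
  class(out) <- c("predator_decomposition", "data.frame")
  out
}

#' Canonical correlation of the two-predator split with prey biomass
#'
#' Finds the linear combination `alpha1 * logT + alpha2 * log((T+L)/T)` of
#' the two predator components that is maximally correlated with log prey
#' biomass. With a single variable on the prey side (q = 1) the canonical
#' correlation equals the multiple correlation coefficient of the
#' regression of log prey on the two predator components — an identity the
#' implementation is tested against.
#'
#' Coefficients are computed under a unit-variance normalisation (each
#' canonical variate has unit sample variance, divisor n - 1), with signs
#' chosen so the canonical correlation is non-negative and the prey-side
#' coefficient positive. [scaled_relationship()] rescales the predator
#' coefficients so the predator variate matches the spread of `k log x`,
#' the convention under which the derived margin slopes are `rho k/alpha`.
#'
#' @param decomp A `predator_decomposition` from [decompose_predators()].
#' @return An object of class `cca_fit` with the unit-variance
#'   coefficients `alpha_unit`, canonical correlation `rho`, dimensions,
#'   sample means and standard deviations, and the prey-side coefficient.
#' @export
fit_cca <- function(decomp) {
  stopifnot(inherits(decomp, "predator_decomposition"))
  n <- nrow(decomp)
  if (n <= 3) stop("need more than 3 joint observations for CCA",
                   call. = FALSE)
  U <- cbind(log_tiger = decomp$log_tiger, log_ratio = decomp$log_ratio)
  v <- decomp$log_prey
  if (sd(v) <= 0) stop("log prey biomass has zero variance", call. = FALSE)
  sds_u <- apply(U, 2, sd)
  if (any(sds_u <= 0))
    stop(sprintf("'%s' has zero variance across records; the joint analysis is degenerate",
                 colnames(U)[sds_u <= 0][1]), call. = FALSE)
  Suu <- cov(U)
  r12 <- Suu[1, 2] / sqrt(Suu[1, 1] * Suu[2, 2])
  if (abs(r12) > 1 - 1e-10)
    stop("log tiger and log ratio components are collinear; canonical directions are not identifiable",
         call. = FALSE)
  Suv <- cov(U, v)           # 2 x 1
  svv <- var(v)

  a_raw <- solve(Suu, Suv)   # direction maximising cor with v
  rho2 <- drop(crossprod(Suv, a_raw)) / svv
  rho <- sqrt(max(rho2, 0))
  # normalise predator variate to unit sample variance
  var_au <- drop(t(a_raw) %*% Suu %*% a_raw)
  a_unit <- drop(a_raw) / sqrt(var_au)
  if (drop(crossprod(a_unit, Suv)) < 0) a_unit <- -a_unit  # make cor >= 0
  names(a_unit) <- c("log_tiger", "log_ratio")

  structure(list(
    alpha_unit = a_unit,
    prey_coef_unit = 1 / sd(v),
    rho = rho,
    n = n, p = 2L, q = 1L,
    means = c(log_tiger = mean(decomp$log_tiger),
              log_ratio = mean(decomp$log_ratio),
              log_prey = mean(v)),
    sds = c(log_tiger = sds_u[["log_tiger"]],
            log_ratio = sds_u[["log_ratio"]],
            log_prey = sd(v)),
    log_prey = v,
    log_base = attr(decomp, "log_base"),
    normalization = "unit-variance"
  ), class = "cca_fit")
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf("Canonical correlation fit (n = %d, p = %d, q = %d)\n",
              x$n, x$p, x$q))
  cat(sprintf("  rho = %.4f\n", x$rho))
  cat(sprintf("  unit-variance coefficients: alpha1 (log T) = %.4f, alpha2 (log (T+L)/T) = %.4f\n",
              x$alpha_unit[1], x$alpha_unit[2]))
  if (!is.null(x$alpha))
    cat(sprintf("  sigma-matched coefficients: alpha1 = %.4f, alpha2 = %.4f (k = %.4f)\n",
                x$alpha[1], x$alpha[2], x$k))
  invisible(x)
}

#' The rho-scaled linear relationship between the canonical variates
#'
#' Combines a CCA fit with the total-predator power-law fit into the
#' relation
#' `alpha1 logT + alpha2 log((T+L)/T) = rho * k * log x + const`.
#' The predator coefficients are rescaled so the predator variate has the
#' same standard deviation as the prey variate `k log x`; with matched
#' spreads the regression slope between the variates is exactly the
#' correlation `rho`, which is what makes the product `rho * k` the slope
#' on log prey biomass. The centering constant is fixed by evaluating the
#' relation at the sample means.
#'
#' @param cca A `cca_fit` (see [fit_cca()]).
#' @param powerfit The total-predator `power_law_fit`, computed on the
#'   same observations (checked).
#' @return A list of class `cca_scaled` with the rescaled coefficients
#'   `alpha`, the slope `rho * k`, the centering constant, and the pieces
#'   (`rho`, `k`, means) they were derived from.
#' @export
scaled_relationship <- function(cca, powerfit) {
  stopifnot(inherits(cca, "cca_fit"), inherits(powerfit, "power_law_fit"))
  if (powerfit$n != cca$n ||
      !isTRUE(all.equal(sort(powerfit$log_x), sort(cca$log_prey),
                        tolerance = 1e-8)))
    stop("the CCA and the power-law fit must be computed on the same observations",
         call. = FALSE)
  if (!identical(cca$log_base, powerfit$log_base))
    stop("log bases of the CCA and the power-law fit differ", call. = FALSE)
  k <- coef(powerfit)[["k"]]
  # predator variate rescaled to sd(k * log x)
  alpha <- cca$alpha_unit * abs(k) * cca$sds[["log_prey"]]
  names(alpha) <- c("alpha1", "alpha2")
  slope <- cca$rho * k
  const <- sum(alpha * cca$means[c("log_tiger", "log_ratio")]) -
    slope * cca$means[["log_prey"]]
  structure(list(
    alpha = alpha, rho = cca$rho, k = k, slope = slope, intercept = const,
    means = cca$means, sd_prey_variate = abs(k) * cca$sds[["log_prey"]],
    log_base = cca$log_base, n = cca$n,
    normalization = "sigma-matched (sd of predator variate = sd of k*logx)"
  ), class = "cca_scaled")
}

#' Wilks' lambda test for the canonical correlation
#'
#' With a single canonical pair, Wilks' lambda is `1 - rho^2`; its
#' significance is assessed by Bartlett's chi-squared approximation
#' `chi^2 = -(n - 1 - (p + q + 1)/2) * ln(lambda)` on `p * q` degrees of
#' freedom.
#'
#' @param rho Canonical correlation in `[0, 1]`.
#' @param n Number of observations (must exceed `p + q + 1`).
#' @param p,q Number of variables on each side (default 2 and 1).
#' @return An object of classes `wilks_test` and `htest` with the lambda
#'   and rho estimates, the Bartlett statistic, degrees of freedom and
#'   upper-tail p-value. `rho = 1` gives an infinite statistic and p = 0.
#'
#' @examples
#' wilks_test(rho = 0.81, n = 15)  # chi^2 = 12.8, p = 0.0017
#' @export
wilks_test <- function(rho, n, p = 2, q = 1) {
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho > 1)
    stop("rho must be a single value in [0, 1]", call. = FALSE)
  if (n <= p + q + 1)
    stop(sprintf("need n > p + q + 1 = %d observations for the Bartlett approximation",
                 p + q + 1), call. = FALSE)
  lambda <- 1 - rho^2
  mult <- n - 1 - (p + q + 1) / 2
  chisq <- if (lambda <= 0) Inf else -mult * log(lambda)
  df <- p * q
  pval <- if (is.infinite(chisq)) 0 else pchisq(chisq, df, lower.tail = FALSE)
  structure(list(
    statistic = c(`Bartlett chi-squared` = chisq),
    parameter = c(df = df),
    p.value = pval,
    estimate = c(`Wilks lambda` = lambda, rho = rho),
    method = "Wilks' lambda test for a single canonical correlation (Bartlett approximation)",
    data.name = sprintf("rho = %g, n = %d, p = %d, q = %d", rho, n, p, q)
  ), class = c("wilks_test", "htest"))
}

#' Marginal (competitor-free) power-law slopes
#'
#' Derives from the scaled relationship the slope of each predator's log
#' biomass in log prey biomass when its competitor is held at its
#' minimum. Setting the leopard component to zero (`L = 0`) gives the
#' tiger margin slope `rho * k / alpha1`; holding tigers at a low
#' reference biomass (default `T = 1` kg/km^2, so `log T = 0`) gives the
#' leopard margin slope `rho * k / alpha2` for the growth of total
#' predator biomass attributable to the leopard component. Margin lines
#' are anchored through the sample means via the relation's centering
#' constant.
#'
#' @param cca A `cca_fit`.
#' @param powerfit The total-predator `power_law_fit` on the same
#'   observations.
#' @param tiger_reference Reference tiger biomass (kg/km^2) for the
#'   leopard margin; 1 by default, near the smallest biomass observed in
#'   lowland surveys.
#' @return An object of class `cca_margins` with slopes and intercepts of
#'   both margin lines (on the fit's log base) and the ingredients used.
#' @export
margins <- function(cca, powerfit, tiger_reference = 1) {
  rel <- scaled_relationship(cca, powerfit)
  a1 <- rel$alpha[["alpha1"]]
  a2 <- rel$alpha[["alpha2"]]
  if (abs(a1) < 1e-12 || abs(a2) < 1e-12)
    stop("a canonical coefficient is zero; the corresponding margin is undefined",
         call. = FALSE)
  if (tiger_reference <= 0)
    stop("tiger_reference must be positive", call. = FALSE)
  l_ref <- log(tiger_reference, base = rel$log_base)

  tiger_slope <- rel$slope / a1
  tiger_intercept <- rel$intercept / a1
  leopard_slope <- rel$slope / a2
  # log(T+L) on the leopard margin = log_ratio + log(T_ref)
  leopard_intercept <- (rel$intercept - a1 * l_ref) / a2 + l_ref

  structure(list(
    tiger_margin_slope = tiger_slope,
    tiger_margin_intercept = tiger_intercept,
    leopard_margin_slope = leopard_slope,
    leopard_margin_intercept = leopard_intercept,
    tiger_reference = tiger_reference,
    alpha = rel$alpha, rho = rel$rho, k = rel$k,
    intercept_const = rel$intercept,
    log_base = rel$log_base,
    x_range = range(cca$log_prey)
  ), class = "cca_margins")
}

#' @export
print.cca_margins <- function(x, ...) {
  cat("Marginal predator-prey slopes from the joint (CCA) fit\n")
  cat(sprintf("  tiger margin  (L = 0):            slope %.4f = rho*k/alpha1 (%.2f x %.2f / %.2f)\n",
              x$tiger_margin_slope, x$rho, x$k, x$alpha[["alpha1"]]))
  cat(sprintf("  leopard margin (T = %g kg/km^2):  slope %.4f = rho*k/alpha2 (%.2f x %.2f / %.2f)\n",
              x$tiger_reference, x$leopard_margin_slope, x$rho, x$k,
              x$alpha[["alpha2"]]))
  invisible(x)
}

#' Predict biomass along a margin line
#'
#' @param margins A `cca_margins` object.
#' @param x Prey biomass densities (kg/km^2).
#' @param species `"tiger"` (margin with no leopards: predicted tiger
#'   biomass) or `"leopard"` (margin with tigers at the reference level:
#'   predicted leopard biomass, i.e. predicted total minus the reference,
#'   floored at zero).
#' @return Predicted biomass densities (kg/km^2).
#' @export
predict_margin <- function(margins, x, species = c("tiger", "leopard")) {
  species <- match.arg(species)
  stopifnot(inherits(margins, "cca_margins"))
  if (any(x <= 0)) stop("prey biomass must be positive", call. = FALSE)
  lx <- log(x, base = margins$log_base)
  b <- margins$log_base
  if (species == "tiger") {
    b^(margins$tiger_margin_intercept + margins$tiger_margin_slope * lx)
  } else {
    total <- b^(margins$leopard_margin_intercept + margins$leopard_margin_slope * lx)
    pmax(total - margins$tiger_reference, 0)
  }
}

#' Competition gap between margin and single-species regression
#'
#' Compares, over a grid of prey biomass values, what a predator is
#' predicted to attain in the absence of its competitor (the margin line)
#' with what the single-species regression says it attains in the
#' competitor's presence. The difference on the biomass scale — the
#' shaded region between the two lines on a log-log plot — is interpreted
#' as the biomass cost of intraguild competition. The gap in the
#' exponents (margin slope minus regression slope) is reported alongside:
#' it is the component of the gap attributable to the competitor's
#' prey-dependent dominance and is zero when the species' shares of
#' predator biomass do not depend on prey biomass.
#'
#' @param margins A `cca_margins` object.
#' @param single_fit The matching single-species `power_law_fit`
#'   (response `"tiger"` or `"leopard"`).
#' @param x_grid Prey biomass grid (kg/km^2); values beyond the observed
#'   prey range are flagged as extrapolation.
#' @param species Which predator; defaults to the fit's response label.
#' @return A `data.frame` of class `competition_gap` with columns `x`,
#'   `margin`, `regression`, `gap` (kg/km^2) and `extrapolated`;
#'   attributes `slope_gap` and `species`.
#' @export
competition_gap <- function(margins, single_fit, x_grid,
                            species = single_fit$response) {
  stopifnot(inherits(margins, "cca_margins"),
            inherits(single_fit, "power_law_fit"))
  if (length(x_grid) == 0) stop("x_grid is empty", call. = FALSE)
  if (any(x_grid <= 0)) stop("x_grid must be positive", call. = FALSE)
  species <- match.arg(species, c("tiger", "leopard"))
  if (!identical(margins$log_base, single_fit$log_base))
    stop("log bases differ between margins and fit", call. = FALSE)
  cf <- coef(single_fit)
  b <- margins$log_base
  lx <- log(x_grid, base = b)
  regression <- b^(cf[["logc"]] + cf[["k"]] * lx)
  margin <- predict_margin(margins, x_grid, species)
  margin_slope <- if (species == "tiger") margins$tiger_margin_slope
                  else margins$leopard_margin_slope
  out <- data.frame(
    x = x_grid,
    margin = margin,
    regression = regression,
    gap = margin - regression,
    extrapolated = lx < margins$x_range[1] | lx > margins$x_range[2]
  )
  attr(out, "species") <- species
  attr(out, "slope_gap") <- margin_slope - cf[["k"]]
  attr(out, "units") <- "kg/km^2"
  class(out) <- c("competition_gap", "data.frame")
  out
}
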