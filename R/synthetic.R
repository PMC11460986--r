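#' Configuration for the synthetic survey generator
#'
#' Describes the statistical structure the analysis assumes: log total
#' predator biomass linear in log prey biomass with Gaussian noise, and
#' total predator biomass partitioned between a dominant and a
#' subordinate species by a prey-dependent share. Defaults emulate the
#' study conditions of the lowland-park surveys: 5 parks x 3 survey
#' years, prey biomass spanning roughly 10^2 to 5 x 10^3 kg/km^2, a
#' generating exponent of 0.75 (the canonical trophic-scaling value),
#' residual spread matched to the interval width such surveys support at
#' n = 15, and a tiger share of predator biomass that rises with prey
#' biomass (dominant predators concentrate where prey are abundant).
#'
#' @param n_parks,n_years Grid of parks and survey years; the generator
#'   yields one record per park-year.
#' @param log_prey_range Range of log10 prey biomass (kg/km^2) sampled
#'   uniformly.
#' @param true_logc,true_k Generating power-law intercept (log10) and
#'   exponent for total predator biomass.
#' @param sigma Residual SD of log10 total predator biomass (>= 0).
#' @param tiger_share_baseline Tiger share of predator biomass at the
#'   centre of the prey range, in (0, 1).
#' @param tiger_share_slope Change of the logit tiger share per log10
#'   unit of prey biomass; positive values make the dominant predator
#'   increasingly dominant where prey are abundant, 0 makes shares
#'   independent of prey.
#' @param share_noise_sd SD of logit-scale noise on the share.
#' @param seed Integer seed; the same configuration and seed give an
#'   identical table.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_parks = 5, n_years = 3,
                             log_prey_range = c(2, log10(5000)),
                             true_logc = -1.8, true_k = 0.75,
                             sigma = 0.3,
                             tiger_share_baseline = 0.75,
                             tiger_share_slope = 0.5,
                             share_noise_sd = 0.3,
                             seed = 1) {
  if (n_parks < 1 || n_years < 1) stop("need at least one park and one year",
                                       call. = FALSE)
  if (length(log_prey_range) != 2 || diff(log_prey_range) < 0)
    stop("log_prey_range must be an increasing pair", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (tiger_share_baseline <= 0 || tiger_share_baseline >= 1)
    stop("tiger_share_baseline must lie strictly in (0, 1)", call. = FALSE)
  if (share_noise_sd < 0) stop("share_noise_sd must be >= 0", call. = FALSE)
  structure(list(n_parks = as.integer(n_parks), n_years = as.integer(n_years),
                 log_prey_range = log_prey_range,
                 true_logc = true_logc, true_k = true_k, sigma = sigma,
                 tiger_share_baseline = tiger_share_baseline,
                 tiger_share_slope = tiger_share_slope,
                 share_noise_sd = share_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic park-year density table
#'
#' For each park-year: draw log10 prey biomass uniformly over the
#' configured range; set log10 total predator biomass to
#' `true_logc + true_k * log10 x` plus Normal(0, sigma^2) noise; draw the
#' tiger share of predator biomass from a logistic model in centred log
#' prey biomass (clamped to (0.01, 0.99)); split the total into tiger and
#' leopard biomass; then invert the biomass construction (divide by body
#' masses, re-apply the per-100-km^2 predator convention) so the returned
#' table is in survey units and can be fed to [read_density_table()]
#' consumers unchanged.
#'
#' The drawn biomass values are attached as attribute `"biomass"`, so the
#' density-to-biomass round trip can be verified to numerical precision.
#'
#' @param config A [synthetic_config()] object.
#' @param weights A [species_weights()] object used for the unit
#'   inversion.
#' @return A `density_table` with `n_parks * n_years` rows; attributes
#'   `biomass` (the generating biomass table) and `config`.
#' @export
generate_dataset <- function(config = synthetic_config(),
                             weights = species_weights()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_parks * config$n_years
  parks <- rep(sprintf("P%02d", seq_len(config$n_parks)),
               each = config$n_years)
  years <- rep(seq(2013, by = 5, length.out = config$n_years),
               times = config$n_parks)

  lx <- runif(n, config$log_prey_range[1], config$log_prey_range[2])
  l_total <- config$true_logc + config$true_k * lx +
    rnorm(n, 0, config$sigma)
  centre <- mean(config$log_prey_range)
  share <- plogis(qlogis(config$tiger_share_baseline) +
                    config$tiger_share_slope * (lx - centre) +
                    rnorm(n, 0, config$share_noise_sd))
  share <- pmin(pmax(share, 0.01), 0.99)

  total <- 10^l_total
  biomass <- data.frame(
    park = parks, year = years,
    tiger_biomass = share * total,
    leopard_biomass = (1 - share) * total,
    prey_biomass = 10^lx,
    prey_mean_weight = weights$prey_mean_weight,
    stringsAsFactors = FALSE
  )
  biomass$predator_biomass <- biomass$tiger_biomass + biomass$leopard_biomass
  if (any(!is.finite(biomass$predator_biomass)) ||
      any(biomass$predator_biomass <= 0))
    stop("configuration produced non-positive or non-finite biomass",
         call. = FALSE)
  class(biomass) <- c("biomass_table", "data.frame")

  densities <- biomass_to_densities(biomass, weights)
  attr(densities, "biomass") <- biomass
  attr(densities, "config") <- config
  densities
}

#' The 2022 study records for Nepal's five lowland parks
#'
#' Returns the five park-year records surveyed in 2022 — tiger and prey
#' densities with their standard errors for Parsa (PNP), Chitwan (CNP),
#' Banke (BaNP), Bardia (BNP) and Shuklaphanta (ShNP). Leopard densities
#' were compiled from separate literature sources and are not part of
#' this fixture, so the records are flagged leopard-missing: they support
#' biomass construction and tiger-only fits but not the joint
#' two-predator analysis.
#'
#' @return A `density_table` with 5 rows, all year 2022, and attribute
#'   `leopard_missing = TRUE`.
#' @export
make_study_fixture <- function() {
  out <- density_table(
    park = c("PNP", "CNP", "BaNP", "BNP", "ShNP"),
    year = rep(2022L, 5),
    tiger_density = c(1.74, 4.06, 0.97, 7.15, 1.99),
    leopard_density = NA,
    prey_density = c(75, 100, 33, 90, 146),
    tiger_density_se = c(0.17, 0.22, 0.12, 0.38, 0.27),
    prey_density_se = c(11.4, 9.1, 6.6, 11.2, 19.0)
  )
  attr(out, "leopard_missing") <- TRUE
  out
}

#' Complete per-observation study table (not distributed)
#'
#' The full 15 park-year table (2013, 2018 and 2022 surveys with leopard
#' densities for every record) is distributed only through the study's
#' external data archive; this package ships only the printed 2022 tiger
#' and prey records (see [make_study_fixture()]). Requesting the complete
#' table therefore raises an informative error; pass a locally obtained
#' copy of the archive's CSV to [read_density_table()] instead.
#'
#' @param complete If `FALSE` (default) return [make_study_fixture()];
#'   if `TRUE`, error as described.
#' @return A `density_table` when `complete = FALSE`.
#' @export
study_density_table <- function(complete = FALSE) {
  if (!complete) return(make_study_fixture())
  stop(paste(
    "the complete per-observation study table (2013/2018 densities and all",
    "leopard densities) is available only from the study's external data",
    "archive and is not distributed with this package; download it and load",
    "it with read_density_table()"), call. = FALSE)
}
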