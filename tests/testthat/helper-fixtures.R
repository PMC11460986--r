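# shared helpers: light MCMC settings for unit tests and seeded fixtures

fast_mcmc <- function(seed = 1, chains = 2, iterations = 4000,
                      burn_in = 1000) {
  mcmc_config(chains = chains, iterations = iterations, burn_in = burn_in,
              seed = seed)
}

# biomass table with the generator's study-scale defaults
make_biomass_fixture <- function(seed = 42, ...) {
  attr(generate_dataset(synthetic_config(seed = seed, ...)), "biomass")
}

# hand-built biomass table (bypasses the generator) for exact constructions
biomass_table_from <- function(tiger, leopard, prey) {
  out <- data.frame(
    park = sprintf("P%02d", seq_along(tiger)),
    year = 2022L,
    tiger_biomass = tiger,
    leopard_biomass = leopard,
    predator_biomass = tiger + leopard,
    prey_biomass = prey,
    prey_mean_weight = 54.43,
    stringsAsFactors = FALSE
  )
  class(out) <- c("biomass_table", "data.frame")
  out
}

# closed-form OLS on the log10 scale, the independent oracle for the fits
ols_loglog <- function(x, y) {
  unname(coef(lm(log10(y) ~ log10(x))))
}
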