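# preypower

Predator–prey biomass power laws and intraguild competition margins for
two-predator systems.

## What it is for

Conservation managers need to know whether the wild-prey base of a
protected area is sufficient to sustain its large carnivores. A robust way
to ask that question is through trophic biomass scaling: across ecosystems,
predator biomass density tends to follow a power law in prey biomass
density,

```
y = c · x^k        ⇔        log y = log c + k · log x,
```

with exponents commonly near `k = 3/4`. `k < 1` implies an increasingly
bottom-heavy biomass pyramid (prey grow proportionally faster than
predators), `k = 1` a constant pyramid shape, `k > 1` top-heaviness.

`preypower` implements this analysis end to end for systems with a
dominant and a subordinate predator sharing one prey base (the motivating
case: tigers and leopards in South Asian lowland parks):

1. **Biomass construction** — park-year survey densities (predators per
   100 km², prey per km²) × mean body masses (tiger 180 kg, leopard 42 kg,
   mean prey weight 54.43 kg) → biomass densities in kg/km².
2. **Bayesian power-law regression** — `log y = log c + k log x` with
   normal priors on the coefficients and an inverse-gamma prior on the
   residual variance, sampled by exact conjugate Gibbs updates (compiled
   code), fitted for total predator, tiger-only and leopard-only biomass.
3. **Joint two-predator analysis** — the exact multiplicative split
   `log(T+L) = log T + log((T+L)/T)` feeds a canonical correlation
   analysis against log prey biomass, giving the relation
   `α₁ log T + α₂ log((T+L)/T) = ρ·k·log x`, a Wilks' Λ / Bartlett χ²
   significance test, the derived *margins* (each species' scaling with
   its competitor held at its minimum: slopes `ρk/α₁` and `ρk/α₂`) and the
   margin-vs-regression *competition gap*.
4. **Synthetic generator and recovery suite** — seeded survey-scale
   datasets with the assumed structure, so every stage is testable and the
   fit is validated by parameter recovery without any external data.

## Worked example

```r
library(preypower)

# printed 2022 survey records for the five lowland parks
densities_to_biomass(make_study_fixture())[, c("park", "tiger_biomass", "prey_biomass")]
#>   park tiger_biomass prey_biomass
#> 1  PNP         3.132     4082.143
#> 2  CNP         7.308     5442.857
#> 3 BaNP         1.746     1796.143
#> 4  BNP        12.870     4898.571
#> 5 ShNP         3.582     7946.571

# closed-form Wilks / Bartlett chain for a canonical correlation
wilks_test(rho = 0.81, n = 15)
#>  Wilks' lambda test for a single canonical correlation (Bartlett approximation)
#> data:  rho = 0.81, n = 15, p = 2, q = 1
#> Bartlett chi-squared = 12.809, df = 2, p-value = 0.001654

# full pipeline on a survey-scale synthetic dataset
d <- generate_dataset(synthetic_config(seed = 11))
a <- run_full_analysis(d, pipeline_config(mcmc = mcmc_config(seed = 11)))
print(a)
#> Predator-prey biomass scaling analysis
#>   records: 15 park-years
#> Bayesian power-law fit (response: total, n = 15, log base 10)
#>   logc  mean  -1.8734  median  -1.8733  95% CI [-2.5052, -1.2489]  Rhat 1.000  ESS 44364
#>   k     mean   0.7270  median   0.7267  95% CI [0.5034, 0.9528]  Rhat 1.000  ESS 44304
#>   ...
#> Canonical correlation fit (n = 15, p = 2, q = 1)
#>   rho = 0.9258
#> ...
```

The total-predator exponent (here 0.727, generated with a true value of
0.75) is the headline quantity: with `k ≈ 0.7`, a fivefold increase in
prey biomass buys roughly a threefold increase in predator biomass
(`predicted_fold_change(0.727, 5)` ≈ 3.2) — a systematically bottom-heavy
pyramid. The tiger and leopard fits, the canonical correlation `ρ`, the
Wilks test, the margin slopes and the competition grid are all part of the
returned object; `plot(a)` draws the log–log scatter with regression,
margin lines and shaded competition gaps.

Real data enter the same way from a CSV with columns `park`, `year`,
`tiger_density_per100km2`, `leopard_density_per100km2`,
`prey_density_perkm2` (see `read_density_table()`); a thin command-line
wrapper with `convert` / `fit` / `cca` / `simulate` / `recover` / `report`
subcommands is installed at `inst/cli/preypower.R`.

See the vignette (`vignettes/trophic-scaling.Rmd`) for the model,
conventions (priors, normalisation, margin anchoring) and limitations.

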