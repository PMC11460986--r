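#' Convert survey densities to biomass densities
#'
#' Multiplies each species' density by its mean body mass, taking care of
#' the survey unit conventions: predator densities are recorded per
#' 100 km^2 and are divided by 100 before weighting, prey densities are
#' already per km^2. The result is a biomass table in kg/km^2 with one row
#' per park-year:
#' tiger biomass `tiger_biomass`, leopard biomass `leopard_biomass`, their
#' sum `predator_biomass`, and prey biomass `prey_biomass`.
#'
#' Records without a leopard density get `NA` leopard and total predator
#' biomass; they stay usable for tiger-only fits and are excluded (with a
#' warning) from joint analyses.
#'
#' @param densities A `density_table` (see [density_table()],
#'   [read_density_table()]).
#' @param weights A [species_weights()] object.
#' @return A `data.frame` of class `biomass_table` with columns `park`,
#'   `year`, `tiger_biomass`, `leopard_biomass`, `predator_biomass`,
#'   `prey_biomass` (all kg/km^2) and the `prey_mean_weight` used per row.
#'
#' @examples
#' d <- density_table(park = "CNP", year = 2022, tiger_density = 4.06,
#'                    prey_density = 100)
#' densities_to_biomass(d)  # tiger 7.308 kg/km^2, prey 5442.9 kg/km^2
#' @export
densities_to_biomass <- function(densities, weights = species_weights()) {
  densities <- validate_density_table(densities)
  stopifnot(inherits(weights, "species_weights"))
  w_tiger <- weights$predator_weights[["tiger"]]
  w_leopard <- weights$predator_weights[["leopard"]]
  w_prey <- ifelse(is.na(densities$prey_mean_weight),
                   weights$prey_mean_weight, densities$prey_mean_weight)

  out <- data.frame(
    park = densities$park,
    year = densities$year,
    tiger_biomass = densities$tiger_density / 100 * w_tiger,
    leopard_biomass = densities$leopard_density / 100 * w_leopard,
    prey_biomass = densities$prey_density * w_prey,
    prey_mean_weight = w_prey,
    stringsAsFactors = FALSE
  )
  out$predator_biomass <- out$tiger_biomass + out$leopard_biomass
  out <- out[, c("park", "year", "tiger_biomass", "leopard_biomass",
                 "predator_biomass", "prey_biomass", "prey_mean_weight")]
  attr(out, "units") <- "kg/km^2"
  attr(out, "leopard_missing") <- any(is.na(out$leopard_biomass))
  class(out) <- c("biomass_table", "data.frame")
  out
}

#' Convert biomass densities back to survey densities
#'
#' Exact inverse of [densities_to_biomass()]: divides biomass by body mass
#' and re-applies the per-100-km^2 predator unit. Used by the synthetic
#' generator so that generated tables are in survey units, and handy for
#' checking the conversion round trip.
#'
#' @param biomass A `biomass_table`.
#' @param weights A [species_weights()] object.
#' @return A `density_table`.
#' @export
biomass_to_densities <- function(biomass, weights = species_weights()) {
  stopifnot(is.data.frame(biomass))
  w_tiger <- weights$predator_weights[["tiger"]]
  w_leopard <- weights$predator_weights[["leopard"]]
  w_prey <- if ("prey_mean_weight" %in% names(biomass)) {
    ifelse(is.na(biomass$prey_mean_weight), weights$prey_mean_weight,
           biomass$prey_mean_weight)
  } else {
    weights$prey_mean_weight
  }
  density_table(
    park = biomass$park,
    year = biomass$year,
    tiger_density = biomass$tiger_biomass / w_tiger * 100,
    leopard_density = biomass$leopard_biomass / w_leopard * 100,
    prey_density = biomass$prey_biomass / w_prey,
    prey_mean_weight = w_prey
  )
}

#' Serialise fit results to JSON
#'
#' Writes a machine-readable summary of one or more fitted objects
#' (power-law fits, CCA fits, Wilks tests, margins) together with run
#' metadata: the seed, and an MD5 hash of the configuration so a result
#' file can be traced to the exact settings that produced it. Numeric
#' values are written at full precision, so two runs with the same seed
#' and configuration produce byte-identical files.
#'
#' @param results A named list of fitted objects and/or plain lists.
#' @param path Output path for the JSON file.
#' @param seed The random seed used for the run (recorded, not applied).
#' @param config Optional configuration object; hashed into the metadata.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(results, path, seed = NULL, config = NULL) {
  stopifnot(is.list(results))
  payload <- list(
    metadata = list(
      package = "preypower",
      version = as.character(utils::packageVersion("preypower")),
      seed = seed,
      config_hash = if (is.null(config)) NULL else .hash_object(config)
    ),
    results = lapply(results, .summarise_for_json)
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON results file
#'
#' @param path Path written by [write_results()].
#' @return A list with elements `metadata` and `results`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# stable MD5 hash of an R object via its serialised JSON form
.hash_object <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(.summarise_for_json(x), tf, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", force = TRUE)
  unname(tools::md5sum(tf))
}

# strip heavy components (posterior draws) and S4/S3 classes for JSON
.summarise_for_json <- function(x) {
  if (inherits(x, "power_law_fit")) {
    return(list(type = "power_law_fit", response = x$response, n = x$n,
                log_base = x$log_base, summary = x$summary,
                rhat = as.list(x$rhat), ess = as.list(x$ess)))
  }
  if (inherits(x, "cca_fit")) {
    return(list(type = "cca_fit", n = x$n, rho = x$rho,
                alpha = as.list(x$alpha), alpha_unit = as.list(x$alpha_unit),
                normalization = x$normalization, k = x$k))
  }
  if (inherits(x, "wilks_test")) {
    return(list(type = "wilks_test", lambda = unname(x$estimate["Wilks lambda"]),
                chisq = unname(x$statistic), df = unname(x$parameter),
                p_value = x$p.value))
  }
  if (inherits(x, "cca_margins")) {
    return(list(type = "cca_margins",
                tiger_margin_slope = x$tiger_margin_slope,
                tiger_margin_intercept = x$tiger_margin_intercept,
                leopard_margin_slope = x$leopard_margin_slope,
                leopard_margin_intercept = x$leopard_margin_intercept,
                tiger_reference = x$tiger_reference, log_base = x$log_base))
  }
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, .summarise_for_json))
  x
}
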