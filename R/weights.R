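#' Species body-weight assumptions
#'
#' Bundle the mean body masses used to convert survey densities
#' (individuals per area) into biomass densities (kg per km^2). The
#' defaults are the values used for Nepal's lowland protected areas:
#' tigers 180 kg and leopards 42 kg, and a seven-species wild-prey
#' assemblage (sambar 212, spotted deer 55, hog deer 40, wild boar 38,
#' barking deer 20, langur 8, rhesus monkey 8 kg).
#'
#' The prey assemblage is summarised by a single mean weight. By default
#' this is the arithmetic mean of the listed prey species (54.43 kg); a
#' different value can be supplied, e.g. when a park's assemblage is known
#' to differ, and [densities_to_biomass()] additionally honours a
#' per-record `prey_mean_weight` column.
#'
#' @param predator_weights Named numeric vector of predator mean body
#'   masses in kg. Must contain `tiger` and `leopard`.
#' @param prey_weights Named numeric vector of prey mean body masses in kg.
#' @param prey_mean_weight Single mean prey weight in kg, or `NULL` to use
#'   the arithmetic mean of `prey_weights`.
#'
#' @return An object of class `species_weights`: a list with elements
#'   `predator_weights`, `prey_weights` and `prey_mean_weight`.
#'
#' @examples
#' w <- species_weights()
#' w$prey_mean_weight  # 54.43 kg
#' @export
species_weights <- function(predator_weights = c(tiger = 180, leopard = 42),
                            prey_weights = c(sambar = 212, spotted_deer = 55,
                                             hog_deer = 40, wild_boar = 38,
                                             barking_deer = 20, langur = 8,
                                             rhesus_monkey = 8),
                            prey_mean_weight = NULL) {
  if (!is.numeric(predator_weights) || is.null(names(predator_weights)))
    stop("`predator_weights` must be a named numeric vector", call. = FALSE)
  if (!all(c("tiger", "leopard") %in% names(predator_weights)))
    stop("`predator_weights` must name both 'tiger' and 'leopard'", call. = FALSE)
  if (!is.numeric(prey_weights) || length(prey_weights) < 1)
    stop("`prey_weights` must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(predator_weights)) || any(predator_weights <= 0))
    stop("all predator weights must be strictly positive", call. = FALSE)
  if (any(!is.finite(prey_weights)) || any(prey_weights <= 0))
    stop("all prey weights must be strictly positive", call. = FALSE)
  if (is.null(prey_mean_weight)) {
    prey_mean_weight <- mean(prey_weights)
  }
  if (!is.numeric(prey_mean_weight) || length(prey_mean_weight) != 1 ||
      !is.finite(prey_mean_weight) || prey_mean_weight <= 0)
    stop("`prey_mean_weight` must be a single positive number", call. = FALSE)
  structure(
    list(predator_weights = predator_weights,
         prey_weights = prey_weights,
         prey_mean_weight = prey_mean_weight),
    class = "species_weights"
  )
}

#' @export
print.species_weights <- function(x, ...) {
  cat("Species body weights (kg)\n")
  cat("  predators:",
      paste(sprintf("%s = %g", names(x$predator_weights), x$predator_weights),
            collapse = ", "), "\n")
  cat("  prey     :",
      paste(sprintf("%s = %g", names(x$prey_weights), x$prey_weights),
            collapse = ", "), "\n")
  cat(sprintf("  mean prey weight: %.2f kg\n", x$prey_mean_weight))
  invisible(x)
}
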