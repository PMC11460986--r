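# Survey-unit conventions used throughout:
#   predator densities are individuals per 100 km^2 (national tiger-survey
#   convention), prey densities are individuals per km^2 (line-transect
#   convention). Biomass is always kg per km^2.

# canonical column names of a density table, in survey units
.density_cols <- c("park", "year", "tiger_density", "leopard_density",
                   "prey_density", "tiger_density_se", "prey_density_se",
                   "prey_mean_weight")

# header names used in CSV files (units spelled out)
.density_csv_cols <- c(
  park              = "park",
  year              = "year",
  tiger_density     = "tiger_density_per100km2",
  leopard_density   = "leopard_density_per100km2",
  prey_density      = "prey_density_perkm2",
  tiger_density_se  = "tiger_density_se_per100km2",
  prey_density_se   = "prey_density_se_perkm2",
  prey_mean_weight  = "prey_mean_weight_kg"
)

#' Construct a park-year density table
#'
#' One row per park-year survey record. Predator densities are individuals
#' per 100 km^2; prey densities are individuals per km^2. Leopard densities
#' may be `NA` (many national surveys report tigers and prey only); such
#' records remain usable for tiger-only analyses and are excluded, with a
#' warning, from analyses that need both predators.
#'
#' @param park Character park identifiers (e.g. `"CNP"`).
#' @param year Integer survey years.
#' @param tiger_density Tiger density, individuals per 100 km^2.
#' @param leopard_density Leopard density, individuals per 100 km^2 (`NA`
#'   when not surveyed).
#' @param prey_density Wild-prey density, individuals per km^2.
#' @param tiger_density_se,prey_density_se Optional standard errors, same
#'   units as the corresponding densities.
#' @param prey_mean_weight Optional per-record mean prey weight (kg)
#'   overriding the assemblage-wide mean in [species_weights()].
#'
#' @return A `data.frame` of class `density_table`.
#' @seealso [read_density_table()], [densities_to_biomass()]
#' @export
density_table <- function(park, year, tiger_density, leopard_density = NA,
                          prey_density, tiger_density_se = NA,
                          prey_density_se = NA, prey_mean_weight = NA) {
  out <- data.frame(
    park = as.character(park),
    year = as.integer(year),
    tiger_density = as.numeric(tiger_density),
    leopard_density = as.numeric(leopard_density),
    prey_density = as.numeric(prey_density),
    tiger_density_se = as.numeric(tiger_density_se),
    prey_density_se = as.numeric(prey_density_se),
    prey_mean_weight = as.numeric(prey_mean_weight),
    stringsAsFactors = FALSE
  )
  class(out) <- c("density_table", "data.frame")
  validate_density_table(out)
}

#' Validate a park-year density table
#'
#' Checks the type invariants of a density table: required columns present,
#' densities and standard errors non-negative, and `(park, year)` pairs
#' unique. Violations raise errors naming the offending record.
#'
#' @param x A `data.frame` with the columns of [density_table()].
#' @return `x`, invisibly classed as `density_table`.
#' @export
validate_density_table <- function(x) {
  required <- c("park", "year", "tiger_density", "prey_density")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0)
    stop("density table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in setdiff(.density_cols, names(x))) x[[col]] <- NA_real_
  x <- x[, .density_cols]

  num_cols <- setdiff(.density_cols, c("park", "year"))
  for (col in num_cols) {
    if (!is.numeric(x[[col]]))
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
  }
  for (col in c("tiger_density", "leopard_density", "prey_density",
                "tiger_density_se", "prey_density_se")) {
    bad <- which(!is.na(x[[col]]) & x[[col]] < 0)
    if (length(bad) > 0)
      stop(sprintf("negative %s in row %d (%s, %s)", col, bad[1],
                   x$park[bad[1]], x$year[bad[1]]), call. = FALSE)
  }
  bad_w <- which(!is.na(x$prey_mean_weight) & x$prey_mean_weight <= 0)
  if (length(bad_w) > 0)
    stop(sprintf("non-positive prey_mean_weight in row %d (%s, %s)",
                 bad_w[1], x$park[bad_w[1]], x$year[bad_w[1]]), call. = FALSE)
  key <- paste(x$park, x$year)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop(sprintf("duplicate (park, year) record in row %d: (%s, %s)",
                 dup[1], x$park[dup[1]], x$year[dup[1]]), call. = FALSE)
  if (!inherits(x, "density_table")) class(x) <- c("density_table", class(x))
  x
}

#' Read a park-year density table from CSV
#'
#' Expects a header with columns `park`, `year`, `tiger_density_per100km2`,
#' `prey_density_perkm2`, and optionally `leopard_density_per100km2`,
#' `tiger_density_se_per100km2`, `prey_density_se_perkm2` and
#' `prey_mean_weight_kg`. Rows are validated (non-negative densities,
#' unique park-year pairs) and errors name the offending CSV row. A file
#' without a leopard column yields records flagged as leopard-missing,
#' which downstream joint analyses skip with notice.
#'
#' @param path Path to a CSV file.
#' @return A `density_table` data frame. The attribute `leopard_missing`
#'   is `TRUE` when the file carried no leopard column.
#' @export
read_density_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- .density_csv_cols[c("park", "year", "tiger_density", "prey_density")]
  missing_cols <- setdiff(unname(required), names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  out <- data.frame(park = as.character(raw$park), stringsAsFactors = FALSE)
  for (internal in setdiff(names(.density_csv_cols), "park")) {
    csv_name <- .density_csv_cols[[internal]]
    if (csv_name %in% names(raw)) {
      v <- raw[[csv_name]]
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value '%s' in column %s, row %d of %s",
                     v[bad[1]], csv_name, bad[1], basename(path)),
             call. = FALSE)
      out[[internal]] <- num
    } else {
      out[[internal]] <- NA_real_
    }
  }
  out$year <- as.integer(out$year)
  leopard_missing <- !(.density_csv_cols[["leopard_density"]] %in% names(raw))
  out <- validate_density_table(out)
  attr(out, "leopard_missing") <- leopard_missing
  out
}

#' Write a park-year density table to CSV
#'
#' Inverse of [read_density_table()]: columns are written under the
#' unit-explicit header names; all-`NA` optional columns are dropped.
#'
#' @param x A `density_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_density_table <- function(x, path) {
  x <- validate_density_table(x)
  out <- as.data.frame(x)
  keep <- vapply(names(.density_csv_cols), function(col) {
    col %in% c("park", "year", "tiger_density", "prey_density") ||
      any(!is.na(out[[col]]))
  }, logical(1))
  out <- out[, names(.density_csv_cols)[keep]]
  names(out) <- unname(.density_csv_cols[keep])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
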