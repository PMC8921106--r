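# Config (YAML/JSON) round-tripping for parameters, physiology and
# scenarios, and CSV export of simulations and observation sets.

#' Write and read a parameter set as YAML
#'
#' The file is a flat map of the `cd_params` fields plus `species`; units
#' are documented in a header comment. Round-trips exactly.
#'
#' @param params A [cd_params()] object.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `read_params()` returns a validated `cd_params`.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cd_params"))
  obj <- unclass(params)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    header <- paste0(
      "# chlordecone PBPK parameter set\n",
      "# units: clearances L/h, rates 1/h, binding capacity ug/L,\n",
      "# partition coefficients and fractions dimensionless\n")
    cat(header, yaml::as.yaml(obj, precision = 15), sep = "", file = path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  species <- obj$species
  obj$species <- NULL
  obj <- lapply(obj, as.numeric)  # YAML reads whole numbers as integer
  do.call(cd_params, c(list(species = species), obj))
}

#' Write and read an exposure scenario as YAML/JSON
#'
#' @param scenario A [exposure_scenario()].
#' @param path File path.
#' @return `read_scenario()` returns a `cd_scenario`; serialisation
#'   round-trips exactly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "cd_scenario"))
  obj <- list(species = scenario$species,
              events = as.list(scenario$events),
              rates = as.list(scenario$rates))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ev <- as.data.frame(obj$events, stringsAsFactors = FALSE)
  ra <- as.data.frame(obj$rates, stringsAsFactors = FALSE)
  exposure_scenario(obj$species,
                    events = if (nrow(ev)) ev else NULL,
                    rates = if (nrow(ra)) ra else NULL)
}

#' Write a physiology object as YAML
#'
#' @param phys A `cd_physiology`.
#' @param path File path.
#' @return `read_physiology()` reconstructs the object (bit-identical
#'   fields).
#' @export
write_physiology <- function(phys, path) {
  stopifnot(inherits(phys, "cd_physiology"))
  obj <- list(species = phys$species, age = phys$age,
              body_weight = phys$body_weight)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_physiology
#' @export
read_physiology <- function(path) {
  obj <- yaml::read_yaml(path)
  physiology_at_age(obj$species, age = obj$age,
                    body_weight = obj$body_weight)
}

#' Export a simulation as tidy CSV
#'
#' Columns: `time_days`, `compartment`, `quantity`
#' (`amount_ug` / `conc_ug_per_L` / `mass_balance_rel`), `value`.
#'
#' @param sim A `cd_simulation`.
#' @param path Output CSV path.
#' @export
write_simulation_csv <- function(sim, path) {
  utils::write.csv(as_tidy_simulation(sim), path, row.names = FALSE)
  invisible(path)
}

#' Read/write observation sets in the calibration CSV schema
#'
#' Columns: `subject`, `time_days`, `matrix`, `value`, `below_lod`, `lod`.
#'
#' @param obs An [observation_set()].
#' @param path CSV path.
#' @export
write_observations_csv <- function(obs, path) {
  stopifnot(inherits(obs, "cd_observations"))
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  observation_set(utils::read.csv(path, stringsAsFactors = FALSE))
}
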