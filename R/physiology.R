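# Species- and age-dependent anatomy/physiology feeding the PBPK model.
# All volumes in L (1 kg tissue ~ 1 L), flows in L/h, body weight in kg,
# age in years.

#' Named compartments of the chlordecone PBPK model
#'
#' @return Character vector of tissue compartment names used throughout the
#'   package: the four permeability-limited tissues (`brain`, `skin`,
#'   `adipose`, `liver`) plus the flow-limited rest-of-body (`rest`).
#' @export
cd_compartments <- function() c("brain", "skin", "adipose", "liver", "rest")

# Default adult anatomy.  Volume fractions are fractions of body weight;
# flow fractions are fractions of cardiac output and sum to 1 over the
# perfused compartments.  Non-perfused mass (bone, hair, gut contents) is
# excluded from the rest-of-body so modelled volumes total `perfused_total`.
.default_anatomy <- list(
  rat = list(
    body_weight = 0.25,
    volume_fraction = c(lung = 0.005, blood = 0.074, brain = 0.0057,
                        skin = 0.19, adipose = 0.07, liver = 0.034),
    flow_fraction = c(brain = 0.02, skin = 0.058, adipose = 0.07,
                      liver = 0.183, rest = 0.669),
    tissue_blood_fraction = c(brain = 0.04, skin = 0.05,
                              adipose = 0.05, liver = 0.15),
    perfused_total = 0.91,
    QCC = 15, QPC = 15
  ),
  human = list(
    body_weight = 70,
    volume_fraction = c(lung = 0.008, blood = 0.079, brain = 0.02,
                        skin = 0.037, adipose = 0.21, liver = 0.026),
    flow_fraction = c(brain = 0.114, skin = 0.058, adipose = 0.052,
                      liver = 0.227, rest = 0.549),
    tissue_blood_fraction = c(brain = 0.04, skin = 0.05,
                              adipose = 0.05, liver = 0.15),
    perfused_total = 0.91,
    QCC = 15, QPC = 15
  )
)

.check_species <- function(species) {
  if (!is.character(species) || length(species) != 1L ||
      !species %in% c("rat", "human")) {
    stop("`species` must be \"rat\" or \"human\"", call. = FALSE)
  }
  species
}

#' Allometric cardiac output and alveolar ventilation
#'
#' Scales cardiac output (QC) and alveolar ventilation (QP) to body weight
#' with the conventional 0.74 allometric exponent, `QC = QCC * BW^0.74`.
#'
#' @param body_weight Body weight (kg), positive.
#' @param QCC,QPC Allometric constants (L/h/kg^0.74); defaults 15.
#' @return Named list with elements `QC` and `QP` (L/h).
#' @examples
#' allometric_flows(0.25) # rat: ~5.38 L/h
#' allometric_flows(70)   # human: ~349 L/h
#' @export
allometric_flows <- function(body_weight, QCC = 15, QPC = 15) {
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0) {
    stop("`body_weight` must be a single positive number", call. = FALSE)
  }
  if (QCC <= 0 || QPC <= 0) stop("flow constants must be positive", call. = FALSE)
  list(QC = QCC * body_weight^0.74, QP = QPC * body_weight^0.74)
}

#' Growth model: quantities as polynomials in age
#'
#' Container for per-quantity polynomial coefficient vectors describing how
#' anatomical quantities change with age, evaluated only inside a stated
#' valid age range.  The default growth model shipped with the package is
#' "static adult" (see [physiology_at_age()]); polynomial tables can be
#' loaded from config so species growth curves can be dropped in.
#'
#' @param coefficients Named list; each element a numeric vector of
#'   polynomial coefficients (intercept first) for one quantity, e.g.
#'   `body_weight`.
#' @param age_range Length-2 numeric, valid age range in years.
#' @param source Character label documenting provenance of the coefficients.
#' @return An object of class `cd_growth_model`.
#' @export
growth_model <- function(coefficients, age_range, source = "user") {
  stopifnot(is.list(coefficients), length(coefficients) > 0,
            !is.null(names(coefficients)))
  if (!is.numeric(age_range) || length(age_range) != 2L ||
      age_range[1] > age_range[2]) {
    stop("`age_range` must be c(min, max) with min <= max", call. = FALSE)
  }
  structure(list(coefficients = lapply(coefficients, as.numeric),
                 age_range = as.numeric(age_range),
                 source = as.character(source)[1]),
            class = "cd_growth_model")
}

#' Evaluate one quantity of a growth model at an age
#'
#' @param model A [growth_model()] object.
#' @param quantity Name of the quantity to evaluate.
#' @param age Age in years; must lie inside the model's valid range.
#' @return The polynomial value; an error if `age` is outside the valid
#'   range or the value is non-positive.
#' @export
evaluate_growth <- function(model, quantity, age) {
  stopifnot(inherits(model, "cd_growth_model"))
  if (age < model$age_range[1] || age > model$age_range[2]) {
    stop(sprintf("age %g outside valid range [%g, %g]",
                 age, model$age_range[1], model$age_range[2]), call. = FALSE)
  }
  coef <- model$coefficients[[quantity]]
  if (is.null(coef)) stop("unknown quantity: ", quantity, call. = FALSE)
  value <- sum(coef * age^(seq_along(coef) - 1L))
  if (!is.finite(value) || value <= 0) {
    stop(sprintf("growth model gives non-positive %s at age %g",
                 quantity, age), call. = FALSE)
  }
  value
}

#' Species physiology at a given age
#'
#' Returns the full anatomical/physiological input set for one species:
#' body weight, compartment volume fractions (of body weight), the
#' tissue-blood sub-compartment fractions of the four permeability-limited
#' tissues, cardiac output, alveolar ventilation and blood-flow fractions.
#' With the default static growth model, adult reference values are
#' returned for any adult age (rat 0.25 kg, human 70 kg); a polynomial
#' [growth_model()] (e.g. loaded from config) can supply age-resolved body
#' weight instead.
#'
#' @param species `"rat"` or `"human"`.
#' @param age Age in years; with the default static model any non-negative
#'   age is accepted and ignored.
#' @param growth A [growth_model()] or `NULL` for the static adult default.
#' @param body_weight Optional explicit body weight (kg) overriding both
#'   the default and the growth model.
#' @return An object of class `cd_physiology`: list with `species`, `age`,
#'   `body_weight`, `volume_fraction`, `tissue_blood_fraction`,
#'   `flow_fraction`, `perfused_total`, `QC`, `QP`, and absolute `volumes`
#'   (L) and `flows` (L/h) per compartment.
#' @examples
#' phys <- physiology_at_age("rat")
#' phys$body_weight # 0.25 kg
#' @export
physiology_at_age <- function(species, age = NULL, growth = NULL,
                              body_weight = NULL) {
  .check_species(species)
  anat <- .default_anatomy[[species]]
  if (is.null(age)) age <- if (species == "rat") 1 else 35
  if (!is.null(growth)) {
    bw <- evaluate_growth(growth, "body_weight", age)
  } else {
    if (age < 0) stop("age must be non-negative", call. = FALSE)
    bw <- anat$body_weight
  }
  if (!is.null(body_weight)) bw <- body_weight
  if (!is.finite(bw) || bw <= 0) stop("body weight must be positive", call. = FALSE)

  vf <- anat$volume_fraction
  if (sum(vf) > anat$perfused_total) {
    stop("named volume fractions exceed the perfused total", call. = FALSE)
  }
  vf <- c(vf, rest = anat$perfused_total - sum(vf))
  fl <- allometric_flows(bw, anat$QCC, anat$QPC)
  flows <- anat$flow_fraction * fl$QC

  phys <- structure(list(
    species = species,
    age = age,
    body_weight = bw,
    volume_fraction = vf,
    tissue_blood_fraction = anat$tissue_blood_fraction,
    flow_fraction = anat$flow_fraction,
    perfused_total = anat$perfused_total,
    QCC = anat$QCC, QPC = anat$QPC,
    QC = fl$QC, QP = fl$QP,
    volumes = vf * bw,
    flows = flows
  ), class = "cd_physiology")
  validate_physiology(phys)
}

#' Validate a physiology object
#'
#' Checks the invariants of a `cd_physiology` object: positive body weight,
#' positive volume fractions summing to the perfused total, flow fractions
#' summing to one, positive QC/QP.
#'
#' @param phys A `cd_physiology` object.
#' @param strict If `FALSE`, the flow-fraction sum check is skipped
#'   (used internally during one-at-a-time sensitivity perturbation).
#' @return `phys`, invisibly on success; error otherwise.
#' @export
validate_physiology <- function(phys, strict = TRUE) {
  stopifnot(inherits(phys, "cd_physiology"))
  if (phys$body_weight <= 0) stop("body_weight must be > 0", call. = FALSE)
  if (any(phys$volume_fraction <= 0)) {
    stop("all volume fractions must be > 0", call. = FALSE)
  }
  if (sum(phys$volume_fraction) > 1 + 1e-9) {
    stop("volume fractions sum above 1", call. = FALSE)
  }
  if (strict && abs(sum(phys$flow_fraction) - 1) > 1e-9) {
    stop("blood-flow fractions must sum to 1", call. = FALSE)
  }
  if (phys$QC <= 0 || phys$QP <= 0) stop("QC and QP must be > 0", call. = FALSE)
  if (any(phys$tissue_blood_fraction <= 0 | phys$tissue_blood_fraction >= 1)) {
    stop("tissue blood fractions must be in (0, 1)", call. = FALSE)
  }
  invisible(phys)
}

#' Convert a dietary concentration to a body-weight-normalised dose rate
#'
#' Dimensional arithmetic: `diet_ppm` (mg chemical per kg food) times daily
#' food intake (kg food/day) divided by body weight (kg) gives
#' mg/kg bw/day.
#'
#' @param diet_ppm Concentration in food (mg/kg, i.e. ppm), non-negative.
#' @param food_intake Food intake (kg/day), non-negative.
#' @param body_weight Body weight (kg), positive.
#' @return Dose rate in mg/kg bw/day.
#' @examples
#' diet_ppm_to_dose(5, 0.025, 0.25) # 0.5 mg/kg bw/day
#' @export
diet_ppm_to_dose <- function(diet_ppm, food_intake, body_weight) {
  if (diet_ppm < 0 || food_intake < 0) {
    stop("diet_ppm and food_intake must be non-negative", call. = FALSE)
  }
  if (!is.finite(body_weight) || body_weight <= 0) {
    stop("body_weight must be positive", call. = FALSE)
  }
  diet_ppm * food_intake / body_weight
}

#' @export
print.cd_physiology <- function(x, ...) {
  cat(sprintf("<cd_physiology> %s, age %g y, BW %g kg, QC %.3g L/h, QP %.3g L/h\n",
              x$species, x$age, x$body_weight, x$QC, x$QP))
  cat("volumes (L):\n")
  print(round(x$volumes, 4))
  invisible(x)
}
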