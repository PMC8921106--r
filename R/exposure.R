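# Exposure scenarios: route switches, bolus dose events and continuous
# dietary rates. Doses are specified per kg body weight and converted to
# absolute ug at simulation start using the frozen body weight.

#' Construct an exposure scenario
#'
#' An exposure scenario couples route switches with a schedule of bolus
#' dose events (oral gavage or intravenous) and/or continuous dietary dose
#' rates with start/stop times. Dietary exposure is modelled as a
#' zero-order input into the absorbing gut lumen (animals feed throughout
#' the day); gavage is an instantaneous lumen bolus; IV enters blood
#' directly.
#'
#' @param species `"rat"` or `"human"`.
#' @param events Data frame with columns `time` (h), `route`
#'   (`"oral_gavage"` or `"intravenous"`), `dose` (ug/kg bw), or `NULL`.
#' @param rates Data frame with columns `start`, `stop` (h) and `rate`
#'   (ug/kg bw/day, dietary), or `NULL`.
#' @param allow_unvalidated_routes Inhalation/dermal events are rejected
#'   unless this is `TRUE` (those routes ship structurally but unvalidated).
#' @return Object of class `cd_scenario`.
#' @export
exposure_scenario <- function(species = c("human", "rat"), events = NULL,
                              rates = NULL, allow_unvalidated_routes = FALSE) {
  species <- match.arg(species)
  if (is.null(events)) {
    events <- data.frame(time = numeric(), route = character(),
                         dose = numeric(), stringsAsFactors = FALSE)
  }
  if (is.null(rates)) {
    rates <- data.frame(start = numeric(), stop = numeric(),
                        rate = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("time", "route", "dose") %in% names(events)),
            all(c("start", "stop", "rate") %in% names(rates)))
  known <- c("oral_gavage", "intravenous", "inhalation", "dermal")
  if (nrow(events)) {
    if (!all(events$route %in% known)) {
      stop("unknown route(s): ",
           paste(setdiff(events$route, known), collapse = ", "), call. = FALSE)
    }
    if (any(events$route %in% c("inhalation", "dermal")) &&
        !allow_unvalidated_routes) {
      stop("inhalation/dermal routes are unvalidated; set ",
           "`allow_unvalidated_routes = TRUE` to accept them", call. = FALSE)
    }
    if (any(events$time < 0)) stop("event times must be >= 0", call. = FALSE)
    if (any(events$dose < 0)) stop("bolus doses must be >= 0", call. = FALSE)
    events <- events[order(events$time), , drop = FALSE]
    rownames(events) <- NULL
  }
  if (nrow(rates)) {
    if (any(rates$rate < 0)) stop("dose rates must be >= 0", call. = FALSE)
    if (any(rates$stop <= rates$start)) {
      stop("rate windows need stop > start", call. = FALSE)
    }
  }
  switches <- c(
    oral_gavage = any(events$route == "oral_gavage"),
    dietary = nrow(rates) > 0,
    intravenous = any(events$route == "intravenous"),
    inhalation = any(events$route == "inhalation"),
    dermal = any(events$route == "dermal")
  )
  structure(list(species = species, events = events, rates = rates,
                 switches = switches),
            class = "cd_scenario")
}

#' Single oral gavage dose
#'
#' @param dose Dose in ug/kg bw (use `mg_per_kg()` for mg/kg inputs).
#' @param t0 Dose time (h), default 0.
#' @param species `"rat"` or `"human"`.
#' @return `cd_scenario` with one gavage event and all other routes off.
#' @examples
#' single_oral(mg_per_kg(40), species = "rat") # classical 40 mg/kg design
#' @export
single_oral <- function(dose, t0 = 0, species = c("human", "rat")) {
  species <- match.arg(species)
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  ev <- if (dose > 0) {
    data.frame(time = t0, route = "oral_gavage", dose = dose,
               stringsAsFactors = FALSE)
  } else NULL
  exposure_scenario(species, events = ev)
}

#' Single intravenous bolus
#'
#' @inheritParams single_oral
#' @return `cd_scenario` with one IV event; the dose enters blood directly,
#'   bypassing the gut.
#' @export
iv_bolus <- function(dose, t0 = 0, species = c("human", "rat")) {
  species <- match.arg(species)
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  ev <- if (dose > 0) {
    data.frame(time = t0, route = "intravenous", dose = dose,
               stringsAsFactors = FALSE)
  } else NULL
  exposure_scenario(species, events = ev)
}

#' Repeated daily oral (dietary) exposure
#'
#' Constant daily dose represented by default as a continuous zero-order
#' dietary input (equivalent to discrete daily boluses at steady state to
#' within ~2%); set `discrete = TRUE` for one gavage bolus per 24 h.
#'
#' @param dose_rate Dose rate (ug/kg bw/day).
#' @param start,stop Window (h), `stop > start`.
#' @param species `"rat"` or `"human"`.
#' @param discrete Use daily boluses instead of a continuous rate.
#' @return `cd_scenario`.
#' @examples
#' repeated_daily_oral(0.007, 0, days(1000)) # FWI Gr.2-style scenario
#' @export
repeated_daily_oral <- function(dose_rate, start, stop,
                                species = c("human", "rat"),
                                discrete = FALSE) {
  species <- match.arg(species)
  if (dose_rate < 0) stop("dose_rate must be >= 0", call. = FALSE)
  if (stop <= start) stop("stop must be > start", call. = FALSE)
  if (discrete) {
    times <- seq(start, stop - 1e-9, by = 24)
    ev <- data.frame(time = times, route = "oral_gavage", dose = dose_rate,
                     stringsAsFactors = FALSE)
    return(exposure_scenario(species, events = ev))
  }
  exposure_scenario(species,
                    rates = data.frame(start = start, stop = stop,
                                       rate = dose_rate))
}

#' Unit helpers
#'
#' `days()` converts days to the model's internal hours; `mg_per_kg()`
#' converts mg/kg bw to the internal ug/kg bw.
#'
#' @param x Numeric value(s).
#' @return Converted numeric.
#' @export
days <- function(x) x * 24

#' @rdname days
#' @export
mg_per_kg <- function(x) x * 1000

#' Total administered dose of a scenario
#'
#' Analytic bookkeeping: sum of bolus events plus the integral of the
#' continuous rates, up to time `t`.
#'
#' @param scenario A `cd_scenario`.
#' @param t End time (h).
#' @param body_weight Body weight (kg) used to convert per-kg doses to ug.
#' @return Administered amount (ug).
#' @export
administered_dose <- function(scenario, t, body_weight) {
  stopifnot(inherits(scenario, "cd_scenario"))
  ev <- scenario$events
  ra <- scenario$rates
  total <- 0
  if (nrow(ev)) total <- total + sum(ev$dose[ev$time <= t])
  if (nrow(ra)) {
    dur <- pmax(0, pmin(ra$stop, t) - ra$start)   # hours
    total <- total + sum(ra$rate / 24 * dur)
  }
  total * body_weight
}

#' @export
print.cd_scenario <- function(x, ...) {
  on <- names(x$switches)[x$switches]
  cat(sprintf("<cd_scenario> %s; routes on: %s\n", x$species,
              if (length(on)) paste(on, collapse = ", ") else "none (zero dose)"))
  if (nrow(x$events)) {
    cat(sprintf("  %d bolus event(s), total %g ug/kg\n",
                nrow(x$events), sum(x$events$dose)))
  }
  if (nrow(x$rates)) {
    cat(sprintf("  %d continuous rate window(s)\n", nrow(x$rates)))
  }
  invisible(x)
}
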