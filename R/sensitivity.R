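# Local one-at-a-time sensitivity screen:
# SA% = 100 * (Cplasma_perturbed - Cplasma_baseline) / Cplasma_baseline,
# where Cplasma is the whole-blood CD concentration at the end of a chronic
# oral exposure of 1e-3 ug/kg bw/day for 655 days (five assumed half-lives)
# and each parameter is varied multiplicatively by (1 +/- delta).

.default_sa_scenario <- function(species = "human") {
  repeated_daily_oral(1e-3, 0, days(655), species = species)
}

# rebuild a physiology object with one scalar multiplied by `factor`
.perturb_physiology <- function(phys, name, factor) {
  named_vf <- phys$volume_fraction[setdiff(names(phys$volume_fraction), "rest")]
  anat <- list(vf = named_vf, tbf = phys$tissue_blood_fraction,
               qf = phys$flow_fraction, QCC = phys$QCC, QPC = phys$QPC,
               perfused_total = phys$perfused_total)
  if (name %in% c("QCC", "QPC", "perfused_total")) {
    anat[[name]] <- anat[[name]] * factor
  } else if (grepl("^vf_", name)) {
    anat$vf[sub("^vf_", "", name)] <- anat$vf[sub("^vf_", "", name)] * factor
  } else if (grepl("^tbf_", name)) {
    anat$tbf[sub("^tbf_", "", name)] <- anat$tbf[sub("^tbf_", "", name)] * factor
  } else if (grepl("^qf_", name)) {
    anat$qf[sub("^qf_", "", name)] <- anat$qf[sub("^qf_", "", name)] * factor
  } else {
    stop("unknown physiology scalar: ", name, call. = FALSE)
  }
  bw <- phys$body_weight
  vf <- c(anat$vf, rest = unname(anat$perfused_total - sum(anat$vf)))
  if (vf["rest"] <= 0) stop("perturbation exhausts rest-of-body volume",
                            call. = FALSE)
  QC <- anat$QCC * bw^0.74
  out <- phys
  out$volume_fraction <- vf
  out$tissue_blood_fraction <- anat$tbf
  out$flow_fraction <- anat$qf
  out$perfused_total <- anat$perfused_total
  out$QCC <- anat$QCC; out$QPC <- anat$QPC
  out$QC <- QC; out$QP <- anat$QPC * bw^0.74
  out$volumes <- vf * bw
  out$flows <- anat$qf * QC
  validate_physiology(out, strict = FALSE)
}

.perturbed_inputs <- function(param_name, factor, params, physiology) {
  if (grepl("^phys:", param_name)) {
    list(params = params,
         physiology = .perturb_physiology(physiology,
                                          sub("^phys:", "", param_name),
                                          factor))
  } else {
    if (is.null(params[[param_name]]) || param_name == "species") {
      stop("unknown parameter: ", param_name, call. = FALSE)
    }
    value <- params[[param_name]] * factor
    if (param_name %in% .fraction_params && value > 1) {
      warning(param_name, " clipped to 1 after perturbation", call. = FALSE)
      value <- 1
    }
    if (param_name == "BIND" && value >= 1) value <- 1 - 1e-12
    p <- params
    p[[param_name]] <- value
    list(params = p, physiology = physiology)
  }
}

.sa_endpoint <- function(params, physiology, scenario, end_time) {
  sim <- simulate_cd(scenario, params, physiology, duration = end_time,
                     times = c(end_time / 2, end_time))
  sim$conc$blood_total[nrow(sim$conc)]
}

#' Percent change of the steady-exposure blood concentration under a
#' single-parameter perturbation
#'
#' Runs the chronic sensitivity scenario twice (baseline and with one
#' parameter multiplied by `1 + direction * delta`) and returns
#' `100 * (C_perturbed - C_baseline)/C_baseline`, `C` being the whole-blood
#' CD concentration at the final exposure day.
#'
#' @param param_name Parameter to perturb: a `cd_params` field or a
#'   physiology scalar prefixed `"phys:"` (e.g. `"phys:qf_liver"`); see
#'   [sa_manifest()].
#' @param direction `+1` or `-1`.
#' @param delta Relative perturbation (default 0.05, i.e. 5%).
#' @param scenario Chronic exposure scenario; default 1e-3 ug/kg bw/day for
#'   655 days.
#' @param params,physiology Baseline inputs.
#' @param baseline Optional precomputed baseline endpoint (used by
#'   [sa_screen()] to avoid rerunning it).
#' @return SA% (scalar).
#' @export
sa_percent <- function(param_name, direction = +1, delta = 0.05,
                       scenario = NULL, params = human_params(),
                       physiology = physiology_at_age(params$species),
                       baseline = NULL) {
  stopifnot(direction %in% c(-1, 1), delta > 0)
  if (is.null(scenario)) scenario <- .default_sa_scenario(params$species)
  end_time <- max(scenario$rates$stop, scenario$events$time)
  if (is.null(baseline)) {
    baseline <- .sa_endpoint(params, physiology, scenario, end_time)
  }
  if (baseline <= 0) {
    stop("baseline blood concentration is zero; SA% undefined", call. = FALSE)
  }
  pert <- .perturbed_inputs(param_name, 1 + direction * delta, params,
                            physiology)
  val <- .sa_endpoint(pert$params, pert$physiology, scenario, end_time)
  100 * (val - baseline) / baseline
}

#' One-at-a-time sensitivity screen over the parameter manifest
#'
#' Runs [sa_percent()] in both directions for every parameter of
#' [sa_manifest()] and reports the sensitive set: parameters whose larger
#' absolute response exceeds `threshold` percent. Ordering is
#' deterministic: by decreasing `max_abs`, ties broken by name.
#'
#' @param params,physiology Baseline inputs (shipped human set by default).
#' @param threshold Sensitivity threshold in percent (default 0.2).
#' @param delta Relative perturbation (default 0.05).
#' @param scenario Chronic exposure scenario; default 1e-3 ug/kg bw/day for
#'   655 days.
#' @param manifest Character vector of parameters to screen.
#' @return Object of class `cd_sensitivity`: list with `table` (data frame:
#'   parameter, sa_plus, sa_minus, max_abs, sensitive, error), `sensitive`
#'   (character vector), `threshold`, `delta` and the scenario descriptor.
#' @export
sa_screen <- function(params = human_params(),
                      physiology = physiology_at_age(params$species),
                      threshold = 0.2, delta = 0.05, scenario = NULL,
                      manifest = sa_manifest()) {
  if (is.null(scenario)) scenario <- .default_sa_scenario(params$species)
  end_time <- max(scenario$rates$stop, scenario$events$time)
  baseline <- .sa_endpoint(params, physiology, scenario, end_time)
  rows <- lapply(manifest, function(nm) {
    res <- tryCatch({
      sp <- sa_percent(nm, +1, delta, scenario, params, physiology, baseline)
      sm <- sa_percent(nm, -1, delta, scenario, params, physiology, baseline)
      list(sa_plus = sp, sa_minus = sm, error = NA_character_)
    }, error = function(e) {
      list(sa_plus = NA_real_, sa_minus = NA_real_,
           error = conditionMessage(e))
    })
    data.frame(parameter = nm, sa_plus = res$sa_plus, sa_minus = res$sa_minus,
               max_abs = max(abs(c(res$sa_plus, res$sa_minus))),
               error = res$error, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$sensitive <- !is.na(tab$max_abs) & tab$max_abs > threshold
  ord <- order(-ifelse(is.na(tab$max_abs), -Inf, tab$max_abs), tab$parameter)
  tab <- tab[ord, c("parameter", "sa_plus", "sa_minus", "max_abs",
                    "sensitive", "error")]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 sensitive = tab$parameter[tab$sensitive],
                 threshold = threshold, delta = delta,
                 baseline = baseline,
                 scenario = sprintf(
                   "constant oral %g ug/kg bw/day for %g days",
                   sum(scenario$rates$rate), end_time / 24)),
            class = "cd_sensitivity")
}

#' @export
print.cd_sensitivity <- function(x, ...) {
  cat(sprintf("<cd_sensitivity> %s; delta %.3g, threshold %.3g%%\n",
              x$scenario, x$delta, x$threshold))
  cat(sprintf("sensitive set (%d): %s\n", length(x$sensitive),
              paste(x$sensitive, collapse = ", ")))
  print(utils::head(transform(x$table,
                              sa_plus = signif(sa_plus, 3),
                              sa_minus = signif(sa_minus, 3),
                              max_abs = signif(max_abs, 3)), 10))
  invisible(x)
}
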