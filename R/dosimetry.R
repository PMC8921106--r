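# Forward/reverse dosimetry and kinetic summary statistics.

#' Reverse dosimetry: external dose from a steady-state blood concentration
#'
#' Estimates the constant oral dose (ug/kg bw/day) that produces a target
#' steady-state blood CD concentration. The model response is probed at a
#' unit-scale dose; if doubling the dose doubles the steady-state blood
#' concentration to within 1% (linear regime, which holds for all
#' population-survey scale targets), the dose is returned by proportional
#' scaling. Otherwise bisection on the dose is used, with bracket doubling
#' until the target is enclosed.
#'
#' @param target_css Target steady-state blood concentration (ug/L), >= 0.
#' @param params,physiology Model inputs (use the calibrated human set for
#'   population applications).
#' @param exposure_days Constant-exposure duration defining "steady state"
#'   (days); 1000 by default.
#' @param probe_dose Unit-scale probe dose (ug/kg bw/day) for the linearity
#'   check.
#' @return Object of class `cd_reverse_dose`: list with `target_css`,
#'   `dose` (ug/kg bw/day), `converged`, `linear`, `residual` (ug/L:
#'   achieved minus target steady-state blood concentration).
#' @examples
#' \donttest{
#' phys <- physiology_at_age("human")
#' reverse_dose(0.42, human_params(), phys)$dose # ~0.007 ug/kg bw/day
#' }
#' @export
reverse_dose <- function(target_css, params, physiology,
                         exposure_days = 1000, probe_dose = 0.01) {
  if (target_css < 0) stop("target_css must be >= 0", call. = FALSE)
  if (target_css == 0) {
    return(structure(list(target_css = 0, dose = 0, converged = TRUE,
                          linear = TRUE, residual = 0),
                     class = "cd_reverse_dose"))
  }
  css_at <- function(d) {
    unname(steady_state_concentrations(d, params, physiology,
                                       n_days = exposure_days)["blood_total"])
  }
  c1 <- css_at(probe_dose)
  if (c1 <= 0) stop("model gives zero blood concentration at the probe dose",
                    call. = FALSE)
  c2 <- css_at(2 * probe_dose)
  linear <- abs(c2 - 2 * c1) / (2 * c1) <= 0.01
  if (linear) {
    dose <- target_css * probe_dose / c1
    achieved <- css_at(dose)
    res <- achieved - target_css
    if (abs(res) <= 1e-3 * target_css) {
      return(structure(list(target_css = target_css, dose = dose,
                            converged = TRUE, linear = TRUE, residual = res),
                       class = "cd_reverse_dose"))
    }
  }
  # bisection with bracket expansion
  lo <- 0; f_lo <- -target_css
  hi <- max(probe_dose, target_css * probe_dose / c1)
  f_hi <- css_at(hi) - target_css
  it <- 0
  while (f_hi < 0 && it < 60) {
    hi <- 2 * hi
    f_hi <- css_at(hi) - target_css
    it <- it + 1
  }
  if (f_hi < 0) {
    stop("target blood concentration not enclosable (model ceiling)",
         call. = FALSE)
  }
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    f_mid <- css_at(mid) - target_css
    if (abs(f_mid) <= 1e-3 * target_css) {
      return(structure(list(target_css = target_css, dose = mid,
                            converged = TRUE, linear = linear,
                            residual = f_mid),
                       class = "cd_reverse_dose"))
    }
    if (f_mid < 0) lo <- mid else hi <- mid
  }
  structure(list(target_css = target_css, dose = (lo + hi) / 2,
                 converged = FALSE, linear = linear, residual = f_mid),
            class = "cd_reverse_dose")
}

#' @export
print.cd_reverse_dose <- function(x, ...) {
  cat(sprintf(
    "<cd_reverse_dose> Css %.4g ug/L -> %.4g ug/kg bw/day (%s, %s)\n",
    x$target_css, x$dose,
    if (x$converged) "converged" else "NOT converged",
    if (x$linear) "linear regime" else "bisection"))
  invisible(x)
}

#' Terminal half-life from a simulated blood profile
#'
#' Least-squares regression of log blood concentration against time on a
#' stated window; the half-life is `ln(2)/|slope|`. The window must contain
#' at least 5 grid points with strictly positive, decreasing
#' concentrations.
#'
#' @param sim A `cd_simulation`.
#' @param window Length-2 numeric, window in days (e.g. `c(14, 56)`).
#' @return Half-life in days.
#' @examples
#' \donttest{
#' phys <- physiology_at_age("rat")
#' sim <- simulate_cd(single_oral(mg_per_kg(40), species = "rat"),
#'                    rat_params(), phys, duration = days(84))
#' terminal_half_life(sim, c(14, 56)) # ~21 days
#' }
#' @export
terminal_half_life <- function(sim, window) {
  stopifnot(inherits(sim, "cd_simulation"), length(window) == 2L)
  d <- sim$conc
  keep <- d$time_days >= window[1] & d$time_days <= window[2]
  if (sum(keep) < 5L) {
    stop("need at least 5 grid points inside the window", call. = FALSE)
  }
  cb <- d$blood_total[keep]
  tt <- d$time_days[keep]
  if (any(cb <= 0)) {
    stop("blood concentration not strictly positive on the window",
         call. = FALSE)
  }
  if (any(diff(cb) >= 0)) {
    stop("blood concentration not monotonically decreasing on the window; ",
         "choose a later window", call. = FALSE)
  }
  slope <- stats::coef(stats::lm(log(cb) ~ tt))[["tt"]]
  log(2) / abs(slope)
}

#' Cumulative excretion fractions
#'
#' Cumulative faecal and urinary excretion at time `t`, as percent of the
#' administered dose.
#'
#' @param sim A `cd_simulation`.
#' @param t_days Time (days) within the simulated range.
#' @return Named numeric: `faecal_pct`, `urinary_pct`, and `body_pct` (the
#'   remaining body burden, so the three sum to 100).
#' @export
excretion_fractions <- function(sim, t_days) {
  stopifnot(inherits(sim, "cd_simulation"))
  if (t_days < 0 || t_days > max(sim$days)) {
    stop("t_days outside the simulated range", call. = FALSE)
  }
  i <- which.min(abs(sim$days - t_days))
  adm <- sim$states[i, "administered"]
  if (adm <= 0) {
    return(c(faecal_pct = 0, urinary_pct = 0, body_pct = 0))
  }
  body <- sum(sim$states[i, .body_states])
  c(faecal_pct = unname(100 * sim$states[i, "faeces"] / adm),
    urinary_pct = unname(100 * sim$states[i, "urine"] / adm),
    body_pct = unname(100 * body / adm))
}
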