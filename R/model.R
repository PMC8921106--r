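# Seven-compartment chlordecone PBPK model: lungs, blood, brain, skin,
# adipose, liver, rest-of-body, plus the extravascular lipoprotein and
# lymphatic circulation (ELPLC) sub-compartment and a three-pool gut lumen
# (absorbing proximal segment, non-absorbing distal segment, metabolite
# pool).
#
# Brain, skin, adipose and liver are permeability-limited: each is split
# into a tissue-blood sub-compartment exchanging with systemic blood by
# flow, and a cellular matrix exchanging with tissue blood through a
# permeability-area product. Lung and rest-of-body are flow-limited. Only
# free blood CD (fraction 1 - BIND) exchanges or is cleared. Hepatic CDBP
# binding is saturable and, together with biliary excretion, is driven by
# the blood-equivalent free liver concentration (tissue free / P_liver).
#
# Units: ug, L, hours.

.state_names <- c("blood", "lymph", "lung",
                  "brain_b", "brain_t", "skin_b", "skin_t",
                  "adipose_b", "adipose_t", "liver_b", "liver_t",
                  "rest", "lumen_prox", "lumen_dist", "lumen_met",
                  "met_produced", "faeces", "urine", "absorbed",
                  "administered")

# Cumulative bookkeeping states excluded from the in-body mass balance.
.body_states <- c("blood", "lymph", "lung", "brain_b", "brain_t", "skin_b",
                  "skin_t", "adipose_b", "adipose_t", "liver_b", "liver_t",
                  "rest", "lumen_prox", "lumen_dist", "lumen_met")

# Precompute everything the RHS needs into a flat list.
.build_context <- function(params, physiology) {
  p <- params
  ph <- physiology
  V <- ph$volumes
  tbf <- ph$tissue_blood_fraction
  fl <- ph$flows
  list(
    fu = 1 - p$BIND,
    V_bl = unname(V["blood"]),
    V_lung = unname(V["lung"]), P_lung = p$P_lung,
    Q_lung = ph$QC,
    V_br_b = unname(V["brain"] * tbf["brain"]),
    V_br_t = unname(V["brain"] * (1 - tbf["brain"])),
    V_sk_b = unname(V["skin"] * tbf["skin"]),
    V_sk_t = unname(V["skin"] * (1 - tbf["skin"])),
    V_fa_b = unname(V["adipose"] * tbf["adipose"]),
    V_fa_t = unname(V["adipose"] * (1 - tbf["adipose"])),
    V_li_b = unname(V["liver"] * tbf["liver"]),
    V_li_t = unname(V["liver"] * (1 - tbf["liver"])),
    V_re = unname(V["rest"]),
    Q_br = unname(fl["brain"]), Q_sk = unname(fl["skin"]),
    Q_fa = unname(fl["adipose"]), Q_li = unname(fl["liver"]),
    Q_re = unname(fl["rest"]),
    P_br = p$P_brain, P_sk = p$P_skin, P_fa = p$P_adipose,
    P_li = p$P_liver, P_re = p$P_rest,
    PA_br = p$PA_brain, PA_sk = p$PA_skin, PA_fa = p$PA_adipose,
    PA_li = p$PA_liver,
    LIB = p$LIBMAXCD1, KD = p$KD_LIV,
    CL_bile = p$CL_bile, KBILE = p$KBILE, F_reab = p$F_reab,
    f_reconv = p$f_reconv,
    ka = p$KA * p$k_abs, KST = p$KST, k_fec = p$k_fec,
    f_prox = p$f_prox, f_dist = p$f_dist,
    f_lymph = p$f_lymph, k_lymph = p$k_lymph,
    k_ent = p$k_ent, k_urine = p$k_urine,
    BW = ph$body_weight
  )
}

# Blood-equivalent free liver concentration from total tissue concentration.
# Total = P*x + LIB*x/(KD + x); solve the quadratic for the non-negative
# root x.
.liver_free_eq <- function(total, P, LIB, KD) {
  b <- P * KD + LIB - total
  (-b + sqrt(b * b + 4 * P * KD * total)) / (2 * P)
}

# Fast RHS used by the integrator; `rate_oral`/`rate_iv` are constant
# zero-order inputs (ug/h) over the current integration segment.
.cd_rhs <- function(t, y, ctx, rate_oral = 0, rate_iv = 0) {
  C_b <- y[1L] / ctx$V_bl
  C_f <- ctx$fu * C_b

  C_lung_eq <- y[3L] / (ctx$V_lung * ctx$P_lung)
  J_lung <- ctx$Q_lung * (C_f - C_lung_eq)

  C_br_b <- y[4L] / ctx$V_br_b
  J_br_in <- ctx$Q_br * (C_f - C_br_b)
  J_br_ex <- ctx$PA_br * (C_br_b - y[5L] / (ctx$V_br_t * ctx$P_br))

  C_sk_b <- y[6L] / ctx$V_sk_b
  J_sk_in <- ctx$Q_sk * (C_f - C_sk_b)
  J_sk_ex <- ctx$PA_sk * (C_sk_b - y[7L] / (ctx$V_sk_t * ctx$P_sk))

  C_fa_b <- y[8L] / ctx$V_fa_b
  J_fa_in <- ctx$Q_fa * (C_f - C_fa_b)
  J_fa_ex <- ctx$PA_fa * (C_fa_b - y[9L] / (ctx$V_fa_t * ctx$P_fa))

  C_li_b <- y[10L] / ctx$V_li_b
  x_li <- .liver_free_eq(y[11L] / ctx$V_li_t, ctx$P_li, ctx$LIB, ctx$KD)
  J_li_in <- ctx$Q_li * (C_f - C_li_b)
  J_li_ex <- ctx$PA_li * (C_li_b - x_li)
  J_bile <- ctx$CL_bile * x_li

  C_re_eq <- y[12L] / (ctx$V_re * ctx$P_re)
  J_re <- ctx$Q_re * (C_f - C_re_eq)

  J_abs <- ctx$ka * y[13L]
  J_transit <- ctx$KST * y[13L]
  J_met_out <- ctx$KST * y[15L]
  J_ent <- ctx$k_ent * C_f
  J_ur <- ctx$k_urine * C_f
  J_bile_par <- (1 - ctx$KBILE) * J_bile
  J_bile_met <- ctx$KBILE * J_bile

  dy <- numeric(20L)
  dy[1L] <- -J_lung - J_br_in - J_sk_in - J_fa_in - J_li_in - J_re +
    ctx$k_lymph * y[2L] - J_ent - J_ur + rate_iv
  dy[2L] <- ctx$f_lymph * J_abs - ctx$k_lymph * y[2L]
  dy[3L] <- J_lung
  dy[4L] <- J_br_in - J_br_ex
  dy[5L] <- J_br_ex
  dy[6L] <- J_sk_in - J_sk_ex
  dy[7L] <- J_sk_ex
  dy[8L] <- J_fa_in - J_fa_ex
  dy[9L] <- J_fa_ex
  dy[10L] <- J_li_in - J_li_ex + (1 - ctx$f_lymph) * J_abs
  dy[11L] <- J_li_ex - J_bile
  dy[12L] <- J_re
  dy[13L] <- ctx$f_prox * rate_oral + ctx$F_reab * J_bile_par +
    ctx$f_reconv * J_met_out - J_abs - J_transit
  dy[14L] <- ctx$f_dist * rate_oral + J_transit + J_ent - ctx$k_fec * y[14L]
  dy[15L] <- J_bile_met - J_met_out
  dy[16L] <- J_bile_met
  dy[17L] <- ctx$k_fec * y[14L] + (1 - ctx$F_reab) * J_bile_par +
    (1 - ctx$f_reconv) * J_met_out
  dy[18L] <- J_ur
  dy[19L] <- J_abs
  dy[20L] <- rate_oral + rate_iv
  dy
}

#' State-vector time derivative of the PBPK model
#'
#' Evaluates the right-hand side of the model ODEs for a given state.
#' Intended for inspection and testing; [simulate_cd()] integrates the same
#' equations.
#'
#' @param state Named numeric vector over [cd_state_names()] (ug), or an
#'   unnamed vector in that order.
#' @param t Time (h).
#' @param params [cd_params()] set.
#' @param physiology [physiology_at_age()] object.
#' @param scenario [exposure_scenario()]; its continuous rates define the
#'   zero-order input at `t` (bolus events are instantaneous and do not
#'   appear in the derivative).
#' @return Named derivative vector (ug/h).
#' @export
cd_derivatives <- function(state, t, params, physiology, scenario = NULL) {
  if (!is.null(names(state))) state <- state[.state_names]
  if (length(state) != 20L || anyNA(state)) {
    stop("state must cover all ", length(.state_names), " model amounts",
         call. = FALSE)
  }
  if (any(state < 0)) {
    stop("negative state amount(s): ",
         paste(.state_names[state < 0], collapse = ", "), call. = FALSE)
  }
  ctx <- .build_context(params, physiology)
  rate_oral <- 0
  if (!is.null(scenario) && nrow(scenario$rates)) {
    act <- scenario$rates$start <= t & t < scenario$rates$stop
    rate_oral <- sum(scenario$rates$rate[act]) / 24 * ctx$BW
  }
  dy <- .cd_rhs(t, unname(state), ctx, rate_oral = rate_oral)
  if (anyNA(dy) || any(!is.finite(dy))) {
    stop("non-finite derivative for state(s): ",
         paste(.state_names[!is.finite(dy)], collapse = ", "), call. = FALSE)
  }
  names(dy) <- .state_names
  dy
}

#' Names of the model state amounts
#' @return Character vector of the 20 state names (all amounts in ug;
#'   `met_produced`, `faeces`, `urine`, `absorbed`, `administered` are
#'   cumulative ledgers).
#' @export
cd_state_names <- function() .state_names

#' Simulate an exposure scenario
#'
#' Integrates the model with the stiff `lsoda` solver. The timeline is
#' split at every bolus event and dietary-rate boundary and integration is
#' restarted at each discontinuity; bolus doses are added to the lumen
#' (gavage) or blood (IV) at the segment start. A mass-balance ledger is
#' carried along and checked: at every output time
#' `|administered - (in body + excreted)| / max(administered, tiny)` must
#' not exceed `mass_balance_tol`.
#'
#' @param scenario [exposure_scenario()].
#' @param params [cd_params()]; species must match the scenario.
#' @param physiology [physiology_at_age()], frozen for the whole run.
#' @param duration Simulation length (h).
#' @param times Optional output grid (h); default about 500 points plus a
#'   denser early segment.
#' @param rtol,atol Solver tolerances (relative; absolute in ug).
#' @param mass_balance_tol Relative mass-balance tolerance (integrity
#'   check).
#' @return Object of class `cd_simulation`: list with `times` (h), `days`,
#'   `states` (matrix of amounts), `conc` (data frame of derived
#'   concentrations, ug/L), `fluxes` (instantaneous biliary, reabsorption,
#'   enteric, urinary and faecal fluxes, ug/h), `mass_balance` (relative
#'   residual series), plus the inputs.
#' @examples
#' phys <- physiology_at_age("rat")
#' sim <- simulate_cd(iv_bolus(mg_per_kg(1), species = "rat"),
#'                    rat_params(), phys, duration = days(30))
#' max(abs(sim$mass_balance))
#' @export
simulate_cd <- function(scenario, params, physiology, duration,
                        times = NULL, rtol = 1e-8, atol = 1e-12,
                        mass_balance_tol = 1e-6) {
  stopifnot(inherits(scenario, "cd_scenario"), inherits(params, "cd_params"),
            inherits(physiology, "cd_physiology"))
  if (!identical(scenario$species, params$species)) {
    stop("scenario and parameter species differ", call. = FALSE)
  }
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  ev <- scenario$events
  if (nrow(ev) && any(ev$time > duration)) {
    stop("scenario events lie beyond the simulation duration", call. = FALSE)
  }
  if (any(scenario$switches[c("inhalation", "dermal")])) {
    stop("inhalation/dermal routes are structural placeholders and cannot ",
         "be simulated", call. = FALSE)
  }
  ctx <- .build_context(params, physiology)

  if (is.null(times)) {
    early <- 10^seq(-2, log10(min(48, duration)), length.out = 40)
    times <- sort(unique(c(0, early, seq(0, duration, length.out = 481))))
  } else {
    times <- sort(unique(c(0, times)))
    if (max(times) > duration) stop("output times beyond duration", call. = FALSE)
  }

  ra <- scenario$rates
  breaks <- sort(unique(c(0, duration,
                          if (nrow(ev)) ev$time,
                          if (nrow(ra)) c(ra$start, ra$stop))))
  breaks <- breaks[breaks >= 0 & breaks <= duration]

  y <- stats::setNames(numeric(20L), .state_names)
  out <- matrix(NA_real_, nrow = length(times), ncol = 20L,
                dimnames = list(NULL, .state_names))
  if (times[1] == 0) out[1, ] <- y

  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    # apply bolus events at t0
    if (nrow(ev)) {
      here <- which(ev$time == t0)
      for (j in here) {
        amt <- ev$dose[j] * ctx$BW
        tgt <- switch(ev$route[j], oral_gavage = "lumen_prox",
                      intravenous = "blood")
        if (tgt == "lumen_prox") {
          y["lumen_prox"] <- y["lumen_prox"] + params$f_prox * amt
          y["lumen_dist"] <- y["lumen_dist"] + params$f_dist * amt
        } else {
          y[tgt] <- y[tgt] + amt
        }
        y["administered"] <- y["administered"] + amt
      }
    }
    rate_oral <- 0
    if (nrow(ra)) {
      act <- ra$start <= t0 & t1 <= ra$stop
      rate_oral <- sum(ra$rate[act]) / 24 * ctx$BW
    }
    seg_idx <- which(times > t0 & times <= t1)
    seg_times <- unique(c(t0, times[seg_idx], t1))
    sol <- deSolve::lsoda(
      y = unname(y), times = seg_times,
      func = function(t, y, parms) list(.cd_rhs(t, y, ctx, rate_oral)),
      parms = NULL, rtol = rtol, atol = atol, maxsteps = 50000
    )
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("solver failed in segment [%g, %g] h; last good time %g h",
                   t0, t1, max(sol[, 1])), call. = FALSE)
    }
    if (length(seg_idx)) {
      out[seg_idx, ] <- sol[match(times[seg_idx], sol[, 1]), -1, drop = FALSE]
    }
    y[] <- sol[nrow(sol), -1]
    # boluses at exactly t = 0 with times[1] = 0 report the pre-dose state
  }

  # tiny negative round-off from atol is clamped for reporting
  out[out < 0 & out > -atol * 1e3] <- 0

  body <- rowSums(out[, .body_states, drop = FALSE])
  accounted <- body + out[, "faeces"] + out[, "urine"]
  residual <- (out[, "administered"] - accounted) /
    pmax(out[, "administered"], 1e-12)
  if (any(abs(residual) > mass_balance_tol)) {
    stop(sprintf("mass-balance violation: max |residual| = %.3g exceeds %g",
                 max(abs(residual)), mass_balance_tol), call. = FALSE)
  }

  fu <- ctx$fu
  C_b <- out[, "blood"] / ctx$V_bl
  x_li <- .liver_free_eq(out[, "liver_t"] / ctx$V_li_t, ctx$P_li, ctx$LIB,
                         ctx$KD)
  conc <- data.frame(
    time_days = times / 24,
    blood_total = C_b,
    blood_free = fu * C_b,
    brain = (out[, "brain_b"] + out[, "brain_t"]) /
      (ctx$V_br_b + ctx$V_br_t),
    skin = (out[, "skin_b"] + out[, "skin_t"]) / (ctx$V_sk_b + ctx$V_sk_t),
    adipose = (out[, "adipose_b"] + out[, "adipose_t"]) /
      (ctx$V_fa_b + ctx$V_fa_t),
    liver = (out[, "liver_b"] + out[, "liver_t"]) / (ctx$V_li_b + ctx$V_li_t)
  )
  J_bile <- ctx$CL_bile * x_li
  fluxes <- data.frame(
    time_days = times / 24,
    biliary = J_bile,
    reabsorption = ctx$F_reab * (1 - ctx$KBILE) * J_bile,
    enteric = ctx$k_ent * fu * C_b,
    urinary = ctx$k_urine * fu * C_b,
    faecal = ctx$k_fec * out[, "lumen_dist"] +
      (1 - ctx$F_reab) * (1 - ctx$KBILE) * J_bile +
      (1 - ctx$f_reconv) * ctx$KST * out[, "lumen_met"]
  )

  structure(list(times = times, days = times / 24, states = out,
                 conc = conc, fluxes = fluxes, mass_balance = residual,
                 scenario = scenario, params = params,
                 physiology = physiology),
            class = "cd_simulation")
}

#' Steady-state tissue concentrations under constant oral exposure
#'
#' Simulates a constant daily oral dose until steady state and returns the
#' terminal concentrations. Exposure runs for `n_days` (default 1000, about
#' 7.6 terminal half-lives for the human model); a convergence flag is
#' carried if the blood concentration one assumed half-life before the end
#' differs from the terminal value by more than 1%.
#'
#' @param dose_rate Constant oral dose rate (ug/kg bw/day), >= 0.
#' @param params,physiology Model inputs.
#' @param n_days Exposure duration (days).
#' @param half_life_days Assumed terminal half-life used for the
#'   convergence window (days); defaults to 131 (human) or 21 (rat).
#' @return Named numeric vector of terminal concentrations (ug/L) for
#'   blood (total and free), brain, skin, adipose and liver, with
#'   attributes `converged` (logical) and `n_days`.
#' @export
steady_state_concentrations <- function(dose_rate, params, physiology,
                                        n_days = 1000,
                                        half_life_days = NULL) {
  if (dose_rate < 0) stop("dose_rate must be >= 0", call. = FALSE)
  if (is.null(half_life_days)) {
    half_life_days <- if (params$species == "human") 131 else 21
  }
  if (dose_rate == 0) {
    res <- c(blood_total = 0, blood_free = 0, brain = 0, skin = 0,
             adipose = 0, liver = 0)
    attr(res, "converged") <- TRUE
    attr(res, "n_days") <- n_days
    return(res)
  }
  scen <- repeated_daily_oral(dose_rate, 0, days(n_days),
                              species = params$species)
  check_t <- days(c(n_days - half_life_days, n_days))
  sim <- simulate_cd(scen, params, physiology, duration = days(n_days),
                     times = sort(unique(c(seq(0, days(n_days),
                                               length.out = 241), check_t))))
  cc <- sim$conc
  terminal <- cc[nrow(cc), ]
  prev <- cc$blood_total[match(check_t[1] / 24, cc$time_days)]
  converged <- abs(terminal$blood_total - prev) /
    max(terminal$blood_total, 1e-300) <= 0.01
  if (!converged) {
    warning("steady state not reached within ", n_days, " days", call. = FALSE)
  }
  res <- c(blood_total = terminal$blood_total, blood_free = terminal$blood_free,
           brain = terminal$brain, skin = terminal$skin,
           adipose = terminal$adipose, liver = terminal$liver)
  attr(res, "converged") <- converged
  attr(res, "n_days") <- n_days
  res
}

#' @export
print.cd_simulation <- function(x, ...) {
  cat(sprintf("<cd_simulation> %s, %g days, %d output times\n",
              x$params$species, max(x$days), length(x$times)))
  cat(sprintf("  administered %.4g ug; in faeces %.4g ug; in urine %.4g ug\n",
              x$states[nrow(x$states), "administered"],
              x$states[nrow(x$states), "faeces"],
              x$states[nrow(x$states), "urine"]))
  cat(sprintf("  max |mass-balance residual| %.2g\n", max(abs(x$mass_balance))))
  invisible(x)
}

#' Tidy export of a simulation
#'
#' @param sim A `cd_simulation`.
#' @return Long data frame with columns `time_days`, `compartment`,
#'   `quantity` (`amount_ug`, `conc_ug_per_L` or `cum_flux_ug`), `value`,
#'   and the mass-balance residual merged in as quantity
#'   `mass_balance_rel`.
#' @export
as_tidy_simulation <- function(sim) {
  stopifnot(inherits(sim, "cd_simulation"))
  st <- sim$states
  amt <- data.frame(
    time_days = rep(sim$days, ncol(st)),
    compartment = rep(colnames(st), each = nrow(st)),
    quantity = "amount_ug",
    value = as.vector(st)
  )
  cn <- setdiff(names(sim$conc), "time_days")
  conc <- data.frame(
    time_days = rep(sim$conc$time_days, length(cn)),
    compartment = rep(cn, each = nrow(sim$conc)),
    quantity = "conc_ug_per_L",
    value = unlist(sim$conc[cn], use.names = FALSE)
  )
  mb <- data.frame(time_days = sim$days, compartment = "total",
                   quantity = "mass_balance_rel", value = sim$mass_balance)
  rbind(amt, conc, mb)
}
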