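## Multirate integration of the coupled system: the beat-resolved
## cardiac/circulation ODE is integrated to a periodic steady state (fixed-step
## RK4 in compiled code), its beat-averaged pressures and flows are exchanged
## with the slow renal/fluid/hormone ODE, and the slow system is advanced on
## an adaptive macro step of hours-to-days (Heun's method by default, or
## deSolve::lsoda as a verification mode).

#' Compute baseline set-points
#'
#' Runs the healthy baseline beat loop once and anchors every normalization
#' constant of the slow model to it: baseline MAP, venous and capillary
#' pressures, glomerular pressure, distal sodium delivery, the distal
#' reabsorption fraction that closes the sodium balance at the stated intake,
#' the oncotic offset that zeroes transcapillary flux, and the remodeling
#' set-points (the value each driving signal takes at baseline, making the
#' healthy heart exactly remodeling-neutral).
#'
#' @param params `cr_params`; remodeling state is taken as the healthy
#'   reference (`dL = dD = 0`) regardless of its current value
#' @return `cr_params` with `$setpoints` filled
#' @export
compute_setpoints <- function(params) {
  ref <- params
  ref$remodel$dL <- 0; ref$remodel$dD <- 0
  ref$setpoints <- NULL
  beat <- run_beats(ref, record = TRUE)
  h <- hemo_summary(beat, ref)
  if (!h$converged) warning("baseline beat loop did not reach periodicity")
  fl <- params$fluid; re <- params$renal
  rh <- renal_hemodynamics(h$MAP, params, hormones = NULL, P_ven = h$P_ven)
  if (rh$GFR <= 0) stop("baseline parameters give non-positive GFR")
  V_pl0 <- params$blood$BV0 - params$blood$V_rbc
  V_ecf0 <- V_pl0 + fl$V_if0
  load0 <- rh$GFR * fl$cNa_ref / 1000
  MD0 <- load0 * (1 - re$eta_pt)
  U_Na0 <- fl$Na_intake / MIN_PER_DAY          # mmol/min at balance
  one_minus_dt <- U_Na0 / (MD0 * (1 - re$eta_cd))
  if (one_minus_dt <= 0 || one_minus_dt >= 1) {
    stop("cannot close baseline sodium balance; check renal parameters")
  }
  params$renal$eta_dt <- 1 - one_minus_dt
  params$setpoints <- list(
    MAP0 = h$MAP, P_ven0 = h$P_ven, P_cap0 = h$P_cap, CO0 = h$CO,
    P_glom0 = rh$P_glom, GFR0 = rh$GFR, MD0 = MD0,
    sigma_f_ED_0 = h$sigma_f_ED, lambda_f_ED_0 = h$lambda_f_ED,
    sigma_f_peak_0 = h$sigma_f_peak,
    V_pl0 = V_pl0, V_ecf0 = V_ecf0,
    Na0 = fl$cNa_ref * V_ecf0 / 1000,
    pi_d0 = h$P_cap - fl$P_if0,
    water_net_intake = fl$Na_intake / fl$cNa_ref * 1000,  # mL/day
    fast_state0 = beat$state
  )
  params
}

#' Baseline slow state
#' @param params `cr_params` with setpoints
#' @return named numeric vector of slow states
#' @keywords internal
initial_slow_state <- function(params) {
  sp <- params$setpoints
  c(Na = sp$Na0, V_ecf = sp$V_ecf0, V_if = params$fluid$V_if0,
    PRA = 1, ALD = 1, Rauto = 1,
    dL = params$remodel$dL, dD = params$remodel$dD)
}

#' Slow-system derivatives (per day)
#'
#' Assembles one evaluation of the slow right-hand side: solves the fast
#' subsystem to periodicity at the current blood volume and remodeling state,
#' then evaluates renal hemodynamics, tubular handling, fluid exchange, RAAS
#' kinetics, and the remodeling laws.
#'
#' @param y named slow state vector
#' @param params `cr_params` with setpoints
#' @param cache environment holding the warm-start fast state
#' @return list with `deriv` (named vector) and `hemo` diagnostics
#' @keywords internal
slow_derivs <- function(y, params, cache) {
  sp <- params$setpoints
  pr <- params
  pr$remodel$dL <- unname(y["dL"]); pr$remodel$dD <- unname(y["dD"])
  V_pl <- unname(y["V_ecf"] - y["V_if"])
  if (V_pl <= 200) stop("plasma volume collapsed; simulation aborted")
  BV <- V_pl + params$blood$V_rbc
  hormones <- list(ANGII = unname(y["PRA"]), ALD = unname(y["ALD"]))
  rsys_factor <- (1 + params$hormones$k_ang_rsys * (hormones$ANGII - 1)) *
    unname(y["Rauto"])
  beat <- run_beats(pr, state = cache$fast_state, BV = BV,
                    record = TRUE, rsys_factor = rsys_factor)
  cache$fast_state <- beat$state
  h <- hemo_summary(beat, pr)

  RIHP <- renal_interstitial_pressure(h$MAP, h$P_ven, params)
  rh <- renal_hemodynamics(h$MAP, params, hormones, P_ven = h$P_ven)
  cNa <- unname(y["Na"]) / unname(y["V_ecf"]) * 1000
  tub <- tubular_sodium_handling(rh$GFR, cNa, params, hormones, RIHP)
  ra <- raas_feedback(list(PRA = hormones$ANGII, ALD = hormones$ALD),
                      params, rh$P_glom, tub$MD_delivery)
  fluid <- list(V_ecf = unname(y["V_ecf"]), V_if = unname(y["V_if"]),
                Na = unname(y["Na"]))
  fc <- fluid_compartments_rhs(fluid, tub, params, h$P_cap)
  h$J_cap <- fc$J_cap

  rm <- params$remodel
  d_dL <- elongation_rate(rm$mode, rm$K_l, h$sigma_f_ED, h$lambda_f_ED,
                          sp$sigma_f_ED_0, sp$lambda_f_ED_0,
                          rate_max = rm$dL_rate_max)
  d_dD <- if (rm$K_d > 0) {
    diameter_remodeling_rate(h$sigma_f_peak, sp$sigma_f_peak_0, rm$K_d)
  } else 0
  # whole-body flow autoregulation: peripheral resistance adapts slowly so
  # that sustained excess perfusion is converted into pressure, not flow
  auto_target <- max(h$CO / sp$CO0, 0.2)^params$hormones$k_auto
  d_Rauto <- (auto_target - unname(y["Rauto"])) / params$hormones$tau_auto
  deriv <- c(Na = fc$dNa, V_ecf = fc$dV_ecf, V_if = fc$dV_if,
             PRA = ra$dPRA, ALD = ra$dALD, Rauto = d_Rauto,
             dL = d_dL, dD = d_dD)
  if (any(!is.finite(deriv))) stop("non-finite slow derivative")
  h$auto_target <- auto_target
  h$Rauto <- unname(y["Rauto"])
  h$RIHP <- RIHP; h$GFR <- rh$GFR; h$U_Na <- tub$U_Na; h$BV <- BV
  h$ANGII <- ra$ANGII; h$cNa <- cNa
  h$renin_sec <- ra$renin_sec; h$ald_target <- ra$ald_target
  list(deriv = deriv, hemo = h, beat = beat)
}

#' Simulate the coupled cardiorenal system over days
#'
#' Advances the slow (renal/fluid/hormone/remodeling) states with an adaptive
#' Heun scheme, re-solving the beat loop to periodicity at every stage
#' evaluation. Records a daily trajectory of the key observables and applies
#' the steady-state criterion (relative change of LVEDP, MAP, and blood
#' volume below `settle_tol` over the final `settle_window` days).
#'
#' @param params `cr_params`; setpoints are computed from the supplied
#'   `reference` (default: the same parameters) when absent
#' @param days duration in days
#' @param slow_state optional initial slow state (named vector)
#' @param reference optional healthy parameter set used for set-points
#' @param method `"heun"` (adaptive, default) or `"lsoda"` (deSolve
#'   verification mode, fixed output step)
#' @param record_dt trajectory sampling interval (days)
#' @return list with `trajectory` (data.frame), `slow_state`, `params`
#'   (with setpoints), `settled` (logical), `final` (last hemodynamic summary)
#' @export
run_simulation <- function(params, days, slow_state = NULL, reference = NULL,
                           method = c("heun", "lsoda"), record_dt = 1) {
  method <- match.arg(method)
  if (is.null(params$setpoints)) {
    src <- if (is.null(reference)) params else reference
    sps <- compute_setpoints(src)
    params$setpoints <- sps$setpoints
    params$renal$eta_dt <- sps$renal$eta_dt
  }
  if (is.null(slow_state)) slow_state <- initial_slow_state(params)
  cache <- new.env(parent = emptyenv())
  cache$fast_state <- params$setpoints$fast_state0

  rec <- list(); last_rec <- -Inf
  push <- function(t, y, h) {
    rec[[length(rec) + 1]] <<- data.frame(
      t = t, LVEDP = h$LVEDP, MAP = h$MAP, EF = h$EF, CO = h$CO,
      EDV = h$EDV, ESV = h$ESV, BV = h$BV, IFV = unname(y["V_if"]),
      P_ven = h$P_ven, P_pv = h$P_pv, RIHP = h$RIHP, GFR = h$GFR,
      ANGII = h$ANGII, cNa = h$cNa,
      sigma_f_ED = h$sigma_f_ED, lambda_f_ED = h$lambda_f_ED,
      dL = unname(y["dL"]), dD = unname(y["dD"]))
  }

  if (method == "lsoda") {
    rhs <- function(t, y, p) {
      names(y) <- names(slow_state)
      list(slow_derivs(y, params, cache)$deriv)
    }
    times <- seq(0, days, by = record_dt)
    out <- deSolve::lsoda(slow_state, times, rhs, parms = NULL,
                          rtol = 1e-6, atol = 1e-6)
    y <- out[nrow(out), -1]
    names(y) <- names(slow_state)
    for (i in seq_len(nrow(out))) {
      yi <- out[i, -1]; names(yi) <- names(slow_state)
      ev <- slow_derivs(yi, params, cache)
      push(out[i, 1], yi, ev$hemo)
    }
    slow_state <- y
  } else {
    # Heun (explicit trapezoid) on the fluid/sodium/remodeling states with an
    # adaptive macro step; the first-order hormone kinetics are advanced by an
    # exact exponential update (operator splitting), which keeps the fast
    # neurohormonal relaxation out of the step-size control.
    sol <- params$solver
    mass <- c("Na", "V_ecf", "dL", "dD")
    t <- 0; dt <- sol$slow_dt_init
    y <- slow_state
    e1 <- slow_derivs(y, params, cache)
    push(0, y, e1$hemo); last_rec <- 0
    scale <- pmax(abs(y[mass]), c(100, 100, 1, 1))
    while (t < days - 1e-9) {
      dt <- min(dt, days - t, sol$slow_dt_max)
      k1 <- e1$deriv
      y_pred <- y
      y_pred[mass] <- y[mass] + dt * k1[mass]
      y_pred <- hormone_update(y_pred, e1$hemo, dt, params)
      y_pred <- interstitium_update(y_pred, e1$hemo$J_cap, dt, params)
      ok <- TRUE
      e2 <- tryCatch(slow_derivs(y_pred, params, cache),
                     error = function(e) NULL)
      if (is.null(e2)) ok <- FALSE
      if (ok) {
        k2 <- e2$deriv
        y_new <- y
        y_new[mass] <- y[mass] + dt / 2 * (k1[mass] + k2[mass])
        y_new <- hormone_update(y_new, e1$hemo, dt, params,
                                hemo2 = e2$hemo)
        y_new <- interstitium_update(
          y_new, (e1$hemo$J_cap + e2$hemo$J_cap) / 2, dt, params)
        err <- max(abs(k2[mass] - k1[mass]) * dt / 2 / scale)
        if (err > 4 * sol$slow_rel_change && dt > sol$slow_dt_min) ok <- FALSE
      }
      if (!ok) { dt <- max(dt / 2, sol$slow_dt_min); next }
      t <- t + dt
      y <- y_new
      y["dL"] <- max(y["dL"], 0)   # elongation is irreversible
      e1 <- tryCatch(slow_derivs(y, params, cache), error = function(e) NULL)
      if (is.null(e1)) stop("slow integration failed at day ", round(t, 2))
      if (t - last_rec >= record_dt - 1e-9 || t >= days - 1e-9) {
        push(t, y, e1$hemo); last_rec <- t
      }
      if (err < sol$slow_rel_change / 4) dt <- min(dt * 1.5, sol$slow_dt_max)
      else if (err > sol$slow_rel_change) dt <- max(dt / 1.5, sol$slow_dt_min)
    }
    slow_state <- y
  }

  traj <- do.call(rbind, rec)
  settled <- is_settled(traj, params)
  final_ev <- slow_derivs(slow_state, params, cache)
  list(trajectory = traj, slow_state = slow_state, params = params,
       settled = settled, final = final_ev$hemo, final_beat = final_ev$beat,
       fast_state = cache$fast_state)
}

#' Exact first-order hormone update over one macro step
#'
#' Renin and aldosterone relax toward their (slowly varying) targets with
#' fixed time constants; freezing the target over one macro step admits the
#' exact solution, which is unconditionally stable. When both stage
#' evaluations are available the targets are averaged.
#' @keywords internal
hormone_update <- function(y, hemo1, dt, params, hemo2 = NULL) {
  ho <- params$hormones
  sec <- if (is.null(hemo2)) hemo1$renin_sec else
    (hemo1$renin_sec + hemo2$renin_sec) / 2
  ald_t <- if (is.null(hemo2)) hemo1$ald_target else
    (hemo1$ald_target + hemo2$ald_target) / 2
  auto_t <- if (is.null(hemo2)) hemo1$auto_target else
    (hemo1$auto_target + hemo2$auto_target) / 2
  y["PRA"] <- sec + (y["PRA"] - sec) * exp(-dt / ho$tau_renin)
  y["ALD"] <- ald_t + (y["ALD"] - ald_t) * exp(-dt / ho$tau_ald)
  y["Rauto"] <- auto_t + (y["Rauto"] - auto_t) * exp(-dt / ho$tau_auto)
  y
}

#' Linearized exponential update of the interstitial volume
#'
#' Transcapillary exchange equilibrates on hours against a nearly
#' incompliant plasma compartment, which makes it the stiffest slow mode.
#' The flux is linearized in `V_if` (interstitial compliance plus an
#' effective plasma-pressure slope, the solver constant `c_exch`) and
#' relaxed exactly over the macro step. The steady state (zero flux) is
#' unchanged; only the transient is approximated. Exchange moves water
#' between plasma and interstitium, so total body water is conserved
#' exactly.
#' @keywords internal
interstitium_update <- function(y, J_cap, dt, params) {
  fl <- params$fluid
  slope <- fl$K_cap * (1 / fl$C_if + params$solver$c_exch)   # -dJ/dV_if
  rate <- slope * MIN_PER_DAY                                # per day
  dV_eq <- J_cap / slope                                     # V_if* - V_if
  y["V_if"] <- y["V_if"] + (1 - exp(-rate * dt)) * dV_eq
  y
}

#' Steady-state criterion
#'
#' Relative change of LVEDP, MAP, and blood volume below the solver's
#' `settle_tol` over the final `settle_window` days of a trajectory.
#'
#' @param traj trajectory data.frame from [run_simulation()]
#' @param params `cr_params`
#' @return logical
#' @export
is_settled <- function(traj, params) {
  sol <- params$solver
  tend <- max(traj$t)
  if (tend < sol$settle_window) return(FALSE)
  t0 <- tend - sol$settle_window
  i0 <- which.min(abs(traj$t - t0)); i1 <- nrow(traj)
  ok <- vapply(c("LVEDP", "MAP", "BV"), function(v) {
    a <- traj[[v]][i0]; b <- traj[[v]][i1]
    abs(b - a) / max(abs(a), 1e-6) < sol$settle_tol
  }, TRUE)
  all(ok)
}
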