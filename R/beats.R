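## R-side wrapper around the compiled beat integrator, plus the per-beat
## hemodynamic summary used by the slow (renal) loop.

#' @keywords internal
beat_par_list <- function(params, rsys_factor = 1) {
  ca <- params$cardiac; rv <- params$rv; ci <- params$circ
  comp <- ca$composite
  R_sys <- ci$R_sys * rsys_factor
  list(
    c = ca$c, sigma_ar = ca$sigma_ar, beta = ca$beta,
    cf_myo = if (is.null(comp)) ca$c_f else comp$c_f_myo,
    cf_ecm = if (is.null(comp)) ca$c_f else comp$c_f_ecm,
    phi_myo = if (is.null(comp)) 1 else comp$phi_myo,
    phi_ecm = if (is.null(comp)) 0 else comp$phi_ecm,
    V0p = current_V_lv0p(params), Vw = current_V_w(params),
    t_r = ca$t_r, t_f = ca$t_f, dt_f = ca$dt_f, t_beat = ca$t_beat,
    l_s0 = ca$l_s0, l_sf0 = ca$l_sf0, k_fsig = ca$k_fsig,
    v_max = ca$v_max, c_v = ca$c_v, k_len = ca$k_len,
    h_len_max = ca$h_len_max, tau_v = ca$tau_v,
    E_rv = rv$E_rv, C_rv = rv$C_rv, V_rv0 = rv$V_rv0,
    C_sa = ci$C_sa, V0_sa = ci$V0_sa, C_sv = ci$C_sv, V0_sv = ci$V0_sv,
    C_pa = ci$C_pa, V0_pa = ci$V0_pa, C_pv = ci$C_pv, V0_pv = ci$V0_pv,
    R_mit = ci$R_mit, R_av = ci$R_av, R_sys = R_sys,
    R_tri = ci$R_tri, R_pvalve = ci$R_pvalve, R_pulm = ci$R_pulm,
    eps_valve = ci$eps_valve
  )
}

#' Initial distribution of a blood volume over the fast states
#'
#' Chamber volumes and stressed segment volumes are seeded near typical
#' baseline pressures; any remainder is placed in the systemic veins so the
#' states sum exactly to `BV`.
#'
#' @param params `cr_params`
#' @param BV total blood volume to distribute (mL)
#' @return numeric vector of the 7 fast states
#' @keywords internal
initial_fast_state <- function(params, BV = params$blood$BV0) {
  ci <- params$circ
  V_lv <- 110; V_rv <- 110
  V_sa <- ci$V0_sa + ci$C_sa * 90
  V_pa <- ci$V0_pa + ci$C_pa * 15
  V_pv <- ci$V0_pv + ci$C_pv * 8
  V_sv <- BV - (V_lv + V_rv + V_sa + V_pa + V_pv)
  if (V_sv <= 0) stop("blood volume too small to seed the circulation")
  c(V_lv, V_rv, V_sa, V_sv, V_pa, V_pv, 0)
}

#' Run the beat loop to a periodic steady state
#'
#' Integrates the beat-resolved cardiac/circulation ODE with a fixed-step RK4
#' until the start-of-beat state repeats within tolerance, then records one
#' full beat.
#'
#' @param params `cr_params`
#' @param state optional warm-start fast state (7 elements); when `NULL`, a
#'   fresh distribution of `BV` is used
#' @param BV total blood volume (mL); defaults to the parameter baseline
#' @param record whether to record the final beat waveform
#' @param rsys_factor multiplicative neurohormonal factor on systemic
#'   resistance (angiotensin II vasoconstriction; 1 at baseline)
#' @return list with `waveform` (matrix), `state`, `beats`, `converged`
#' @export
run_beats <- function(params, state = NULL, BV = params$blood$BV0,
                      record = TRUE, rsys_factor = 1) {
  sol <- params$solver
  if (is.null(state)) {
    state <- initial_fast_state(params, BV)
  } else {
    # warm start: rebalance the systemic veins so states sum to BV exactly
    state <- as.numeric(state)
    state[4] <- state[4] + (BV - sum(state[1:6]))
    if (state[4] <= 0) state <- initial_fast_state(params, BV)
  }
  cr_run_beats(as.numeric(state), beat_par_list(params, rsys_factor),
               dt = sol$beat_dt, max_beats = sol$max_beats,
               tol = sol$beat_tol, record = record)
}

#' Per-beat hemodynamic summary
#'
#' Reduces a recorded beat to the coupling quantities the slow model needs:
#' mean arterial and venous pressures, capillary interface pressure, cardiac
#' output, end-diastolic stress/stretch, and peak systolic fiber stress.
#' End-diastole is located at mitral-valve closure.
#'
#' @param beat result of [run_beats()] with `record = TRUE`
#' @param params `cr_params`
#' @return named list of summary quantities
#' @export
hemo_summary <- function(beat, params) {
  W <- beat$waveform
  t <- W[, "t"]
  MAP <- mean(W[, "P_sa"])
  P_ven <- mean(W[, "P_sv"])
  P_pv <- mean(W[, "P_pv"])
  P_pa <- mean(W[, "P_pa"])
  CO <- mean(W[, "q_av"]) * 60 / 1000   # L/min
  ev <- valve_events(W)
  EDV <- max(W[, "V_lv"]); ESV <- min(W[, "V_lv"])
  # end-diastole at mitral closure, sub-sample interpolated: the systolic
  # pressure rise is steep, so index quantization alone would jitter LVEDP
  ied <- ev$i_mvc
  ed_at <- function(col) {
    if (is.na(ied)) return(W[which.max(W[, "V_lv"]), col])
    i2 <- if (ied < nrow(W)) ied + 1L else 1L
    q1 <- W[ied, "q_mit"]; q2 <- W[i2, "q_mit"]
    frac <- if (q1 > q2) (q1 - 1) / (q1 - q2) else 0
    frac <- min(max(frac, 0), 1)
    W[ied, col] + frac * (W[i2, col] - W[ied, col])
  }
  LVEDP <- unname(ed_at("P_lv"))
  P_cap <- P_ven + params$circ$w_cap * (MAP - P_ven)
  list(MAP = MAP, P_ven = P_ven, P_pv = P_pv, P_pa = P_pa, P_cap = P_cap,
       CO = CO, EDV = EDV, ESV = ESV, SV = EDV - ESV,
       EF = 100 * (EDV - ESV) / EDV, LVEDP = LVEDP,
       sigma_f_ED = unname(ed_at("sigma_p")),
       lambda_f_ED = unname(ed_at("lambda")),
       sigma_f_peak = max(W[, "sigma_p"] + W[, "sigma_a"]),
       t_ED = if (is.na(ied)) t[which.max(W[, "V_lv"])] else t[ied],
       converged = isTRUE(beat$converged))
}

#' Stressed blood volume of the vascular segments
#'
#' \eqn{\sum_i \max(V_i - V_{i,0}, 0)} over the four vascular segments
#' (chambers excluded), evaluated on the end-of-beat state.
#'
#' @param beat result of [run_beats()]
#' @param params `cr_params`
#' @return volume in mL
#' @export
stressed_blood_volume <- function(beat, params) {
  ci <- params$circ
  y <- beat$state
  v <- c(y[3] - ci$V0_sa, y[4] - ci$V0_sv, y[5] - ci$V0_pa, y[6] - ci$V0_pv)
  sum(pmax(v, 0))
}
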