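## Observables derived from simulated waveforms: valve events, per-beat
## metrics, IVRT and tau estimators, the heart-failure state classifier, and
## the closed-form pressure-stress-strain relations for a thick-walled
## strain-stiffening sphere.

#' Valve events on a periodic beat
#'
#' Events are zero-crossings of the (regularized) valve flows against a small
#' threshold, with the requirement that the preceding open phase carried
#' substantial flow — this suppresses chatter from the smoothed-diode valves.
#' Crossings are cyclic: the beat is treated as periodic.
#'
#' @param W waveform matrix from [run_beats()] (columns `t`, `q_mit`, `q_av`, ...)
#' @param thr flow threshold (mL/s)
#' @return list of indices/times: `i_mvc`, `i_avo`, `i_avc`, `i_mvo` and the
#'   matching `t_*` entries (NA when an event is not resolvable)
#' @export
valve_events <- function(W, thr = 1) {
  t <- W[, "t"]; n <- length(t)
  cyc <- function(i) ((i - 1) %% n) + 1
  crossings <- function(q, rising) {
    qn <- q[cyc(seq_len(n) + 1)]
    if (rising) which(q < thr & qn >= thr) else which(q >= thr & qn < thr)
  }
  # keep only crossings adjacent to a genuine open phase (peak flow >> thr)
  dt_s <- t[2] - t[1]
  n_look <- max(10L, as.integer(round(0.15 / dt_s)))   # 150 ms lookback
  pick <- function(q, idx, rising) {
    if (length(idx) == 0) return(NA_integer_)
    score <- vapply(idx, function(i) {
      win <- cyc(if (rising) i + seq_len(n_look) else i - seq_len(n_look) + 1)
      max(q[win])
    }, 0)
    idx <- idx[score > 10 * thr]
    if (length(idx) == 0) return(NA_integer_)
    idx[1]
  }
  q_mit <- W[, "q_mit"]; q_av <- W[, "q_av"]
  i_mvc <- pick(q_mit, crossings(q_mit, FALSE), FALSE)
  i_avo <- pick(q_av, crossings(q_av, TRUE), TRUE)
  i_avc <- pick(q_av, crossings(q_av, FALSE), FALSE)
  i_mvo <- pick(q_mit, crossings(q_mit, TRUE), TRUE)
  tt <- function(i) if (is.na(i)) NA_real_ else t[i]
  list(i_mvc = i_mvc, i_avo = i_avo, i_avc = i_avc, i_mvo = i_mvo,
       t_mvc = tt(i_mvc), t_avo = tt(i_avo), t_avc = tt(i_avc),
       t_mvo = tt(i_mvo))
}

#' Isovolumic relaxation time
#'
#' Time from aortic-valve closure to mitral-valve opening on a periodic beat
#' (cyclic difference).
#'
#' @param beat result of [run_beats()] with a recorded waveform
#' @param thr valve flow threshold passed to [valve_events()]
#' @return IVRT in milliseconds
#' @export
estimate_ivrt <- function(beat, thr = 1) {
  W <- beat$waveform
  ev <- valve_events(W, thr)
  if (is.na(ev$t_avc) || is.na(ev$t_mvo)) {
    stop("estimate_ivrt: aortic closure / mitral opening not resolvable")
  }
  t_beat <- W[nrow(W), "t"]
  unname(1000 * ((ev$t_mvo - ev$t_avc) %% t_beat))
}

#' Relaxation time constant from a pressure decay
#'
#' Fits the zero-asymptote monoexponential \eqn{P(t) = P_A e^{-t/\tau}}
#' (default) or the three-parameter variant with an additive pressure
#' asymptote \eqn{P_B} to a monotonically decaying pressure segment.
#' Recovers tau exactly on noiseless monoexponential input. The
#' zero-asymptote form is the package default because it reproduces the
#' normal clinical IVRT/tau pairing on the baseline model (see the methods
#' vignette); the asymptote variant remains available for cross-checking.
#'
#' @param t time (s)
#' @param P pressure (mmHg), same length as `t`
#' @param asymptote fit the additive constant `P_B` (default FALSE)
#' @return tau in milliseconds
#' @export
#' @examples
#' t <- seq(0, 0.12, by = 1e-3)
#' estimate_tau_decay(t, 80 * exp(-t / 0.040))            # 40 ms
estimate_tau_decay <- function(t, P, asymptote = FALSE) {
  if (length(t) < 8) stop("estimate_tau_decay: window too short")
  if (P[length(P)] >= P[1]) stop("estimate_tau_decay: window does not decay")
  t <- t - t[1]
  # log-linear start values (assuming small asymptote)
  Pb0 <- if (asymptote) max(min(P) - 0.05 * (max(P) - min(P)), 0) * 0.5 else 0
  pos <- P - Pb0 > 0
  lf <- stats::lm(log(P[pos] - Pb0) ~ t[pos])
  tau0 <- unname(-1 / coef(lf)[2])
  Pa0 <- unname(exp(coef(lf)[1]))
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- (t[length(t)] - t[1]) / 3
  # a start that already fits to numerical precision (noiseless input) is
  # returned directly; nls-type refiners reject zero-residual problems
  rss0 <- sum((P - (Pa0 * exp(-t / tau0) + Pb0))^2)
  if (rss0 < 1e-16 * sum(P^2)) return(1000 * tau0)
  df <- data.frame(t = t, P = P)
  fit <- if (asymptote) {
    minpack.lm::nlsLM(P ~ Pa * exp(-t / tau) + Pb, data = df,
                      start = list(Pa = Pa0, tau = tau0, Pb = Pb0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(P ~ Pa * exp(-t / tau), data = df,
                      start = list(Pa = Pa0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  tau <- coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0) stop("estimate_tau_decay: fit failed")
  1000 * tau
}

#' Relaxation time constant of a simulated beat
#'
#' Extracts the isovolumic-relaxation window — from the time of minimum
#' dP/dt to mitral-valve opening — and fits the monoexponential decay.
#'
#' @param beat result of [run_beats()] with a recorded waveform
#' @param asymptote include the pressure asymptote (default FALSE; see
#'   [estimate_tau_decay()])
#' @param thr valve flow threshold
#' @return tau in milliseconds
#' @export
estimate_tau <- function(beat, asymptote = FALSE, thr = 1) {
  W <- beat$waveform
  ev <- valve_events(W, thr)
  if (is.na(ev$i_avc) || is.na(ev$i_mvo)) {
    stop("estimate_tau: isovolumic relaxation window not resolvable")
  }
  n <- nrow(W)
  idx <- if (ev$i_mvo > ev$i_avc) seq(ev$i_avc, ev$i_mvo) else
    c(seq(ev$i_avc, n), seq_len(ev$i_mvo))
  P <- W[idx, "P_lv"]
  t <- seq_along(idx) * (W[2, "t"] - W[1, "t"])
  dP <- diff(P)
  i0 <- which.min(dP)          # time of most negative dP/dt
  i1 <- length(P)
  if (i1 - i0 < 8) i0 <- max(1, i1 - 20)
  estimate_tau_decay(t[i0:i1], P[i0:i1], asymptote = asymptote)
}

#' Full per-beat metric set
#'
#' @param beat result of [run_beats()] with a recorded waveform
#' @param params `cr_params`
#' @param relaxation also estimate IVRT and tau (slightly more work)
#' @return named list: EF (%), LVEDP, LVEDV, LVESV, SV (mL), CO (L/min), MAP,
#'   systolic/diastolic/pulse pressures (mmHg), IVRT and tau (ms), end-diastolic
#'   fiber stress and stretch, ventricular and arterial elastances, stressed
#'   blood volume (mL)
#' @export
beat_metrics <- function(beat, params, relaxation = TRUE) {
  W <- beat$waveform
  h <- hemo_summary(beat, params)
  ev <- valve_events(W)
  SBP <- max(W[, "P_sa"]); DBP <- min(W[, "P_sa"])
  ivrt <- tau <- NA_real_
  if (relaxation) {
    ivrt <- tryCatch(estimate_ivrt(beat), error = function(e) NA_real_)
    tau <- tryCatch(estimate_tau(beat), error = function(e) NA_real_)
  }
  # elastances referred to the volume origin (the ESPVR intercept is not an
  # observable of the one-fiber model, which can eject below V_lv0p)
  P_es <- if (!is.na(ev$i_avc)) unname(W[ev$i_avc, "P_lv"]) else NA_real_
  E_es <- if (!is.na(P_es)) P_es / h$ESV else NA_real_
  E_a <- if (!is.na(P_es)) P_es / h$SV else NA_real_
  c(h[c("EF", "LVEDP", "EDV", "ESV", "SV", "CO", "MAP",
        "sigma_f_ED", "lambda_f_ED", "sigma_f_peak")],
    list(SBP = SBP, DBP = DBP, pulse_pressure = SBP - DBP,
         IVRT = ivrt, tau = tau, E_es = E_es, E_a = E_a,
         stressed_volume = stressed_blood_volume(beat, params),
         converged = isTRUE(beat$converged)))
}

#' Heart-failure state from EF and LVEDP
#'
#' Partition of the (EF, LVEDP) plane: elevated filling pressure
#' (LVEDP >= 20 mmHg) with EF >= 50% is HFpEF, 40% <= EF < 50% is HF-mEF,
#' EF < 40% is HFrEF; LVEDP < 20 mmHg is non-HF regardless of EF. Boundary
#' ties go to the HF side (LVEDP = 20), the preserved side (EF = 50), and the
#' midrange side (EF = 40).
#'
#' @param EF ejection fraction in percent
#' @param LVEDP end-diastolic pressure in mmHg
#' @return character vector over the labels HFpEF, HF-mEF, HFrEF, non-HF
#' @export
#' @examples
#' classify_hf_state(c(55, 45, 60, 35), c(25, 25, 12, 22))
classify_hf_state <- function(EF, LVEDP) {
  if (any(!is.finite(EF)) || any(!is.finite(LVEDP))) {
    stop("classify_hf_state: inputs must be finite")
  }
  out <- ifelse(LVEDP < 20, "non-HF",
                ifelse(EF >= 50, "HFpEF",
                       ifelse(EF >= 40, "HF-mEF", "HFrEF")))
  out
}

#' Pressure-stress-strain relations for a spherical strain-stiffening vessel
#'
#' For a thick-walled sphere whose wall follows the exponential passive law,
#' wall stress is linearly proportional to the luminal pressure,
#' \eqn{\sigma = 3 P_i / L_0} with the fixed geometry factor
#' \eqn{L_0 = \ln(1 + V_w/V)}, and the wall strain follows by inverting the
#' passive law: \eqn{\epsilon = \ln(1 + \sigma/\beta) / c_f}, which is
#' log-linear in pressure and inversely proportional to stiffness once
#' \eqn{\sigma \gg \beta}.
#'
#' @param P_i luminal pressure (mmHg, > 0); vectorized
#' @param c_f wall stiffness constant
#' @param beta passive stress scale (mmHg)
#' @param geom_factor \eqn{L_0}; default from the baseline LV geometry
#' @return list with `stress` and `strain`
#' @export
spherical_strain_relation <- function(P_i, c_f,
                                      beta = default_parameters()$cardiac$beta,
                                      geom_factor = log(1 + 200 / 120)) {
  if (any(P_i <= 0)) stop("spherical_strain_relation: P_i must be > 0")
  stress <- 3 * P_i / geom_factor
  strain <- log(1 + stress / beta) / c_f
  list(stress = stress, strain = strain)
}
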