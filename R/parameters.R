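#' Default model parameters
#'
#' Builds the full parameter set for the integrated cardiorenal model: cardiac
#' mechanics, right-ventricle and vascular segments, renal hemodynamics and
#' tubular sodium handling, body-fluid compartments, neurohormonal feedback
#' (renin-angiotensin-aldosterone), remodeling laws, and solver settings. The
#' returned object is the single source of truth for baseline and perturbed
#' runs; scenario code derives perturbed copies from it.
#'
#' Printed literature baselines are used where available: fiber stiffness
#' `c_f = 11`, intrinsic contractility `c = 1`, arterial/venous/pulmonary
#' compliances 1.5 / 26.7 / 2.7 / 22 mL/mmHg, venous unstressed volume 3.0 L,
#' preafferent/afferent/efferent renal resistances 14 / 10 / 51 mmHg·min/L,
#' glomerular ultrafiltration coefficient 4.0 mL/min/mmHg, fractional
#' proximal-tubule and collecting-duct sodium reabsorption 66% and 84%, and a
#' renal interstitial hydrostatic pressure set-point of 9.7 mmHg. Remaining
#' constants are calibrated once so the healthy baseline reproduces normal
#' resting physiology (see the methods vignette).
#'
#' @param heart_rate beats per minute (held constant; default 70)
#' @return an object of class `cr_params` (a nested named list)
#' @export
#' @examples
#' p <- default_parameters()
#' p$cardiac$c_f
default_parameters <- function(heart_rate = 70) {
  p <- list(
    cardiac = list(
      c = 1,              # intrinsic contractility (dimensionless)
      sigma_ar = 650,     # active stress scale (mmHg)
      beta = 6.5,         # passive stress scale (mmHg)
      c_f = 11,           # fiber stiffness constant (dimensionless)
      V_lv0 = 60,         # unpressurized LV cavity volume, pre-remodeling (mL)
      V_w = 200,          # LV wall volume (mL)
      t_r = 0.17,         # activation rise duration (s)
      t_f = 0.148,        # normal activation fall duration (s)
      dt_f = 0,           # incremental fall-time extension (s)
      heart_rate = heart_rate,
      t_beat = 60 / heart_rate,
      l_s0 = 2.0,         # sarcomere length at lambda_f = 1 (um)
      l_sf0 = 2.0,        # midpoint of the length-activation sigmoid (um)
      k_fsig = 0.08,      # width of the length-activation sigmoid (um)
      v_max = 14,         # maximum unloaded shortening velocity (um/s)
      c_v = 1.5,          # Hill force-velocity curvature (dimensionless)
      k_len = 0.5,        # eccentric (lengthening) force slope
      h_len_max = 1.4,    # cap on eccentric force enhancement
      tau_v = 0.01,       # velocity-state relaxation time (s)
      composite = NULL    # optional CompositeStiffness (iso-strain two-phase)
    ),
    rv = list(
      E_rv = 0.5,         # peak active elastance (mmHg/mL)
      C_rv = 25,          # diastolic compliance (mL/mmHg)
      V_rv0 = 40          # unstressed volume (mL)
    ),
    circ = list(
      C_sa = 1.5,   V0_sa = 700,   # systemic arterial
      C_sv = 26.7,  V0_sv = 3000,  # systemic venous
      C_pa = 2.7,   V0_pa = 90,    # pulmonary arterial
      C_pv = 22,    V0_pv = 400,   # pulmonary venous
      R_mit = 0.004,      # mitral valve (mmHg*s/mL)
      R_av = 0.006,       # aortic valve
      R_sys = 0.95,       # systemic peripheral resistance
      R_tri = 0.004,      # tricuspid inflow
      R_pvalve = 0.005,   # pulmonic valve
      R_pulm = 0.10,      # pulmonary vascular resistance
      eps_valve = 0.3,    # diode smoothing scale (mmHg)
      w_cap = 0.15        # capillary interface weight between MAP and venous P
    ),
    blood = list(
      BV0 = 5050,         # baseline total blood volume (mL)
      V_rbc = 2000        # red-cell volume, constant (mL)
    ),
    renal = list(
      R_preaff = 14,      # preafferent arteriole resistance (mmHg*min/L)
      R_aff = 10,         # afferent
      R_eff = 51,         # efferent
      R_rv = 6,           # renal venous outflow
      K_f = 4.0,          # glomerular ultrafiltration coefficient (mL/min/mmHg)
      P_filt_offset = 41.6, # Bowman + oncotic opposing pressure (mmHg)
      eta_pt = 0.66,      # fractional proximal-tubule Na reabsorption
      eta_dt = NA_real_,  # distal fraction; solved at baseline for Na balance
      eta_cd = 0.84,      # fractional collecting-duct Na reabsorption
      RIHP0 = 9.7,        # set-point for pressure natriuresis (mmHg)
      rihp_base = 9.7,    # RIHP at baseline pressures (mmHg)
      k_rihp_map = 0.12,  # dRIHP / dMAP
      k_rihp_ven = 0.30,  # dRIHP / d venous pressure
      s_pn_pt = 0.035,    # proximal natriuresis gain (fraction per mmHg RIHP)
      s_pn_cd = 0.050,    # collecting-duct natriuresis gain
      k_ang_pt = 0.08,    # ANG II effect on proximal reabsorption
      k_ald_cd = 0.10,    # aldosterone effect on collecting-duct reabsorption
      k_ang_eff = 0.30,   # ANG II effect on efferent tone
      k_osm = 2.0         # osmotic (ADH) correction gain on water excretion
    ),
    fluid = list(
      Na_intake = 150,    # dietary sodium (mmol/day)
      cNa_ref = 140,      # reference plasma sodium (mmol/L)
      V_if0 = 10500,      # baseline interstitial fluid volume (mL)
      C_if = 500,         # interstitial compliance (mL/mmHg)
      K_cap = 2.0,        # transcapillary filtration coefficient (mL/min/mmHg)
      P_if0 = -3          # baseline interstitial hydrostatic pressure (mmHg)
    ),
    hormones = list(
      tau_renin = 1.0,    # renin relaxation time (day)
      tau_ald = 1.0,      # aldosterone relaxation time (day)
      k_renin_p = 1.5,    # renin sensitivity to glomerular pressure
      k_renin_md = 1,     # renin sensitivity to macula-densa Na delivery
      ald_exp = 0.7,      # aldosterone saturation exponent on ANG II
      renin_min = 0.05,
      renin_max = 20,
      k_ang_rsys = 0.08,  # ANG II effect on systemic resistance
      k_auto = 2,         # whole-body flow autoregulation exponent
      tau_auto = 2        # autoregulation time constant (day)
    ),
    remodel = list(
      mode = "strain",    # {"stress", "strain"} elongation driver
      K_l = 0,            # elongation rate constant (um/day); 0 disables
      K_l_stress = 0.8,   # rate constant used with the stress-driven law
      K_l_strain = 10,    # rate constant used with the strain-driven law
      dL_rate_max = 0.8,  # saturation of the elongation rate (um/day)
      K_d = 0,            # diameter (wall thickening) rate constant (um/day)
      K_d_on = 0.15,
      L_myo0 = 100,       # healthy myocyte length (um)
      D_myo0 = 20,        # healthy myocyte diameter (um)
      dL = 0,             # myocyte elongation Delta L (um)
      dD = 0,             # myocyte diameter change Delta D (um)
      phi_ecm0 = 0.1      # baseline ECM volume fraction of the wall
    ),
    solver = list(
      beat_dt = 2.5e-4,   # RK4 step for the beat loop (s)
      max_beats = 80,     # cap on beats to periodic steady state
      beat_tol = 0.01,    # beat-to-beat state tolerance (mL)
      slow_dt_init = 0.05, # initial macro step (day)
      slow_dt_min = 0.01,
      slow_dt_max = 0.1,
      c_exch = 0.03,      # effective plasma-pressure slope for the interstitium update (mmHg/mL)
      slow_rel_change = 0.01, # per-step relative-change target for adaptivity
      settle_window = 5,  # days over which the steady-state criterion is applied
      settle_tol = 1e-3   # relative change threshold (0.1%)
    ),
    setpoints = NULL      # baseline reference values; see compute_setpoints()
  )
  class(p) <- "cr_params"
  p
}

#' @export
print.cr_params <- function(x, ...) {
  cat("<cr_params> integrated cardiorenal parameter set\n")
  cat("  groups:", paste(setdiff(names(x), "setpoints"), collapse = ", "), "\n")
  cat("  setpoints:", if (is.null(x$setpoints)) "not yet computed" else "computed", "\n")
  invisible(x)
}

#' Apply named parameter overrides
#'
#' Overrides are addressed by dotted keys, `"group.name"` (for example
#' `"cardiac.c_f"`). Unknown groups or names are errors, not warnings, so that
#' misspelled configuration keys cannot silently run a baseline model.
#'
#' @param params a `cr_params` object
#' @param overrides named list (or named numeric vector) of dotted keys
#' @return modified `cr_params`
#' @export
#' @examples
#' p <- set_parameters(default_parameters(), list("cardiac.c_f" = 19.25))
set_parameters <- function(params, overrides) {
  stopifnot(inherits(params, "cr_params"))
  if (length(overrides) == 0) return(params)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
    stop("all overrides must be named by dotted keys, e.g. 'cardiac.c_f'")
  }
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop("invalid parameter key '", key, "': expected 'group.name'")
    }
    grp <- parts[[1]]; nm <- parts[[2]]
    if (is.null(params[[grp]]) || !is.list(params[[grp]])) {
      stop("unknown parameter group '", grp, "' in key '", key, "'")
    }
    if (!nm %in% names(params[[grp]])) {
      stop("unknown parameter '", nm, "' in group '", grp, "' (key '", key, "')")
    }
    params[[grp]][[nm]] <- overrides[[key]]
  }
  if ("heart_rate" %in% vapply(strsplit(names(overrides), ".", fixed = TRUE),
                               function(z) z[2], "")) {
    params$cardiac$t_beat <- 60 / params$cardiac$heart_rate
  }
  validate_parameters(params)
  params
}

#' Validate parameter invariants
#'
#' Checks positivity and timing constraints (for example that the activation
#' rise, fall, and fall extension fit inside one beat).
#'
#' @param params a `cr_params` object
#' @return the parameters, invisibly; signals an error on violation
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "cr_params"))
  ca <- params$cardiac
  chk <- function(ok, what) if (!isTRUE(ok)) stop("invalid parameters: ", what)
  chk(is.finite(ca$c) && ca$c >= 0, "contractility c must be >= 0")
  chk(ca$c_f > 0, "c_f must be > 0")
  chk(ca$beta > 0, "beta must be > 0")
  chk(ca$V_w > 0, "V_w must be > 0")
  chk(ca$V_lv0 > 0, "V_lv0 must be > 0")
  chk(ca$t_r > 0, "t_r must be > 0")
  chk(ca$t_f > 0, "t_f must be > 0")
  chk(ca$dt_f >= 0, "dt_f must be >= 0")
  chk(ca$t_r + ca$t_f + ca$dt_f < ca$t_beat,
      "activation (t_r + t_f + dt_f) must finish within one beat")
  ci <- params$circ
  chk(all(c(ci$C_sa, ci$C_sv, ci$C_pa, ci$C_pv) > 0), "compliances must be > 0")
  chk(all(c(ci$V0_sa, ci$V0_sv, ci$V0_pa, ci$V0_pv) >= 0),
      "unstressed volumes must be >= 0")
  re <- params$renal
  chk(all(c(re$R_preaff, re$R_aff, re$R_eff, re$R_rv) > 0),
      "renal resistances must be > 0")
  chk(re$K_f > 0, "K_f must be > 0")
  chk(re$eta_pt > 0 && re$eta_pt < 1, "eta_pt must be in (0,1)")
  chk(re$eta_cd > 0 && re$eta_cd < 1, "eta_cd must be in (0,1)")
  rm <- params$remodel
  chk(rm$K_l >= 0, "K_l must be >= 0")
  chk(rm$dL >= 0, "dL (myocyte elongation) must be >= 0")
  chk(rm$L_myo0 > 0 && rm$D_myo0 > 0, "myocyte reference geometry must be > 0")
  if (!is.null(ca$composite)) validate_composite(ca$composite)
  invisible(params)
}

#' Zero-pressure LV volume implied by the current remodeling state
#' @param params `cr_params`
#' @return volume in mL
#' @keywords internal
current_V_lv0p <- function(params) {
  zero_pressure_volume(params$cardiac$V_lv0, params$remodel$dL,
                       params$remodel$L_myo0)
}

#' LV wall volume implied by the current remodeling state
#'
#' The wall is myocyte volume (scaling with diameter squared times length)
#' plus a constant ECM volume.
#' @param params `cr_params`
#' @return volume in mL
#' @keywords internal
current_V_w <- function(params) {
  rm <- params$remodel
  V_w0 <- params$cardiac$V_w
  V_myo0 <- (1 - rm$phi_ecm0) * V_w0
  V_ecm0 <- rm$phi_ecm0 * V_w0
  V_myo0 * (1 + rm$dD / rm$D_myo0)^2 * (1 + rm$dL / rm$L_myo0) + V_ecm0
}
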