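## Declarative pathophysiological mechanism perturbations and the two
## simulation protocols: 60-day settling runs (remodeling off) and the
## 1-year outward-remodeling protocol on a mildly hypertensive background.

#' Mechanism names
#' @return character vector of the supported mechanisms
#' @export
mechanism_names <- function() {
  c("lv_stiffness", "contractility", "outward_dilatation", "slowed_relaxation",
    "arterial_compliance", "venous_compliance", "pulm_arterial_compliance",
    "pulm_venous_compliance", "venous_capacitance", "hypertension")
}

#' Construct a mechanism specification
#'
#' A named pathophysiological perturbation with fractional severity in
#' \[0, 1\] spanning the simulated-change range: fiber stiffness +0-75%,
#' contractility -0-20%, outward dilatation +0-25% of baseline myocyte
#' length, relaxation fall-time extension +0-130 ms, each compliance -0-50%,
#' venous unstressed volume -0-50%, and the composite renal hypertension
#' induction (resistances +0-80%, ultrafiltration -0-40%, tubular
#' reabsorption fractions +0-8%, RIHP set-point +0-8%).
#'
#' @param mechanism one of [mechanism_names()]
#' @param severity fraction of the range, in \[0, 1\]
#' @return object of class `cr_mechanism`
#' @export
#' @examples
#' mechanism_spec("lv_stiffness", 1)
mechanism_spec <- function(mechanism, severity) {
  mechanism <- match.arg(mechanism, mechanism_names())
  if (!is.finite(severity) || severity < 0 || severity > 1) {
    stop("severity must lie in [0, 1]")
  }
  structure(list(mechanism = mechanism, severity = severity),
            class = "cr_mechanism")
}

#' Apply a mechanism perturbation to a parameter set
#'
#' Returns a new parameter set with only the mechanism's parameters scaled;
#' severity 0 is the identity. Distinct mechanisms touch disjoint parameters,
#' so applications commute.
#'
#' @param params `cr_params`
#' @param spec `cr_mechanism` from [mechanism_spec()]
#' @return perturbed `cr_params`
#' @export
apply_mechanism <- function(params, spec) {
  stopifnot(inherits(spec, "cr_mechanism"))
  s <- spec$severity
  if (s == 0) return(params)
  switch(spec$mechanism,
    lv_stiffness = {
      params$cardiac$c_f <- params$cardiac$c_f * (1 + 0.75 * s)
      if (!is.null(params$cardiac$composite)) {
        params$cardiac$composite$c_f_myo <-
          params$cardiac$composite$c_f_myo * (1 + 0.75 * s)
        params$cardiac$composite$c_f_ecm <-
          params$cardiac$composite$c_f_ecm * (1 + 0.75 * s)
      }
      params
    },
    contractility = {
      params$cardiac$c <- params$cardiac$c * (1 - 0.20 * s)
      params
    },
    outward_dilatation = {
      params$remodel$dL <- params$remodel$dL +
        0.25 * s * params$remodel$L_myo0
      params
    },
    slowed_relaxation = {
      params$cardiac$dt_f <- params$cardiac$dt_f + 0.130 * s
      params
    },
    arterial_compliance = {
      params$circ$C_sa <- params$circ$C_sa * (1 - 0.5 * s); params
    },
    venous_compliance = {
      params$circ$C_sv <- params$circ$C_sv * (1 - 0.5 * s); params
    },
    pulm_arterial_compliance = {
      params$circ$C_pa <- params$circ$C_pa * (1 - 0.5 * s); params
    },
    pulm_venous_compliance = {
      params$circ$C_pv <- params$circ$C_pv * (1 - 0.5 * s); params
    },
    venous_capacitance = {
      params$circ$V0_sv <- params$circ$V0_sv * (1 - 0.5 * s); params
    },
    hypertension = induce_hypertension(params, s)
  )
}

#' Induce hypertension through renal mechanisms
#'
#' Simultaneously, linearly with severity: renal vascular resistances +0-80%,
#' glomerular ultrafiltration coefficient -0-40%, proximal and
#' collecting-duct fractional sodium reabsorption +0-8%, and the renal
#' interstitial hydrostatic pressure set-point +0-8%. Sodium retention then
#' raises blood volume and arterial pressure mechanistically.
#'
#' @param params `cr_params`
#' @param severity fraction in \[0, 1\]
#' @return perturbed `cr_params`
#' @export
induce_hypertension <- function(params, severity) {
  if (!is.finite(severity) || severity < 0 || severity > 1) {
    stop("severity must lie in [0, 1]")
  }
  s <- severity
  re <- params$renal
  re$R_preaff <- re$R_preaff * (1 + 0.80 * s)
  re$R_aff <- re$R_aff * (1 + 0.80 * s)
  re$R_eff <- re$R_eff * (1 + 0.80 * s)
  re$K_f <- re$K_f * (1 - 0.40 * s)
  re$eta_pt <- re$eta_pt * (1 + 0.08 * s)
  re$eta_cd <- re$eta_cd * (1 + 0.08 * s)
  re$RIHP0 <- re$RIHP0 * (1 + 0.08 * s)
  params$renal <- re
  params
}

#' Apply several mechanisms at once
#' @param params `cr_params`
#' @param specs list of `cr_mechanism`
#' @return perturbed `cr_params`
#' @export
apply_mechanisms <- function(params, specs) {
  for (sp in specs) params <- apply_mechanism(params, sp)
  params
}

#' 60-day settling run
#'
#' Simulates the perturbed model until the slow loop settles to a new stable
#' state, with the remodeling rate constants zeroed throughout (geometry
#' fixed). Set-points are always anchored to the supplied healthy reference.
#'
#' @param params perturbed `cr_params`
#' @param days duration (default 60)
#' @param reference healthy parameter set for set-point anchoring (default:
#'   package baseline at the same heart rate)
#' @param method slow integrator, `"heun"` or `"lsoda"`
#' @return list: `metrics` (full [beat_metrics()] of the settled beat),
#'   `state` (slow state), `trajectory`, `settled`, `hf_state`, `params`
#' @export
run_settling <- function(params, days = 60, reference = NULL,
                         method = "heun") {
  params$remodel$K_l <- 0
  params$remodel$K_d <- 0
  if (is.null(reference)) {
    reference <- default_parameters(heart_rate = params$cardiac$heart_rate)
  }
  sim <- run_simulation(params, days = days, reference = reference,
                        method = method)
  bm <- beat_metrics(sim$final_beat, sim$params)
  hf <- classify_hf_state(bm$EF, bm$LVEDP)
  if (!sim$settled) {
    warning("settling run did not meet the steady-state criterion")
  }
  list(metrics = bm, state = sim$slow_state, trajectory = sim$trajectory,
       settled = sim$settled, hf_state = hf, params = sim$params)
}

#' 1-year outward-remodeling protocol
#'
#' Mild hypertension is induced first and the model equilibrated with
#' outward remodeling off; the insult (for example stiffening or impaired
#' contractility) is then applied, the elongation law enabled, and the model
#' run for one simulated year. Tracks EF, LVEDP, myocyte elongation, and the
#' driving signal against its set-point.
#'
#' @param base_params healthy `cr_params`
#' @param insult `cr_mechanism` (or list of them) applied at year start
#' @param law_mode `"stress"` or `"strain"` elongation driver
#' @param duration remodeling phase length in days (default 365)
#' @param htn_severity severity of the background hypertension (default 0.5,
#'   calibrated to raise settled MAP by roughly 10 mmHg)
#' @param equil_days equilibration length (default 60)
#' @param diameter_remodeling also enable the parallel (wall thickening) law
#'   during the remodeling phase (default TRUE)
#' @return list: `trajectory` (equilibration + remodeling phases, with
#'   `phase` column), `final` metrics, `hf_state`, `params`
#' @export
run_remodeling_protocol <- function(base_params, insult,
                                    law_mode = c("strain", "stress"),
                                    duration = 365, htn_severity = 0.5,
                                    equil_days = 60,
                                    diameter_remodeling = TRUE) {
  law_mode <- match.arg(law_mode)
  if (inherits(insult, "cr_mechanism")) insult <- list(insult)
  p_htn <- induce_hypertension(base_params, htn_severity)
  p_htn$remodel$K_l <- 0; p_htn$remodel$K_d <- 0
  equil <- run_simulation(p_htn, days = equil_days, reference = base_params)

  p_run <- apply_mechanisms(equil$params, insult)
  p_run$remodel$mode <- law_mode
  p_run$remodel$K_l <- if (law_mode == "strain") {
    p_run$remodel$K_l_strain
  } else {
    p_run$remodel$K_l_stress
  }
  p_run$remodel$K_d <- if (diameter_remodeling) p_run$remodel$K_d_on else 0
  sim <- run_simulation(p_run, days = duration,
                        slow_state = equil$slow_state)

  eq_tr <- equil$trajectory; eq_tr$phase <- "equilibration"
  eq_tr$t <- eq_tr$t - max(eq_tr$t)
  rm_tr <- sim$trajectory; rm_tr$phase <- "remodeling"
  traj <- rbind(eq_tr, rm_tr)
  bm <- beat_metrics(sim$final_beat, sim$params)
  list(trajectory = traj, final = bm,
       hf_state = classify_hf_state(bm$EF, bm$LVEDP),
       params = sim$params, slow_state = sim$slow_state)
}
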