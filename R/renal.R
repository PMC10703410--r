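## Kidney and body-fluid model: renal hemodynamics, segment-wise tubular
## sodium handling with pressure natriuresis, transcapillary fluid exchange,
## and renin-angiotensin-aldosterone feedback. This is a reduced formulation
## built around the printed renal baselines (series arteriolar resistances,
## ultrafiltration coefficient, fractional reabsorptions, RIHP set-point); all
## normalization constants are anchored to the healthy baseline steady state
## so that baseline hormone and fluid derivatives are exactly zero.

#' Renal interstitial hydrostatic pressure
#'
#' Rises with renal perfusion (arterial) pressure and with venous congestion;
#' equals its baseline value at baseline pressures.
#'
#' @param MAP mean arterial pressure (mmHg)
#' @param P_ven systemic venous pressure (mmHg)
#' @param params `cr_params` with computed setpoints
#' @return RIHP in mmHg
#' @export
renal_interstitial_pressure <- function(MAP, P_ven, params) {
  re <- params$renal; sp <- params$setpoints
  re$rihp_base + re$k_rihp_map * (MAP - sp$MAP0) +
    re$k_rihp_ven * (P_ven - sp$P_ven0)
}

#' Renal hemodynamics
#'
#' Series-resistance renal blood flow, glomerular capillary pressure, and
#' glomerular filtration rate \eqn{GFR = K_f (P_{glom} - P_{offset})}.
#' Angiotensin II constricts the efferent arteriole.
#'
#' @param MAP mean arterial pressure (mmHg); must exceed venous pressure
#' @param params `cr_params`
#' @param hormones list with normalized `ANGII` (baseline 1); `NULL` for baseline
#' @param P_ven systemic venous pressure (mmHg)
#' @return list with `RBF` (L/min), `P_glom` (mmHg), `GFR` (mL/min)
#' @export
renal_hemodynamics <- function(MAP, params, hormones = NULL, P_ven = 4) {
  re <- params$renal
  ang <- if (is.null(hormones)) 1 else hormones$ANGII
  R_eff <- re$R_eff * (1 + re$k_ang_eff * (ang - 1))
  R_tot <- re$R_preaff + re$R_aff + R_eff + re$R_rv
  dP <- MAP - P_ven
  if (dP <= 0) {
    warning("renal_hemodynamics: non-positive perfusion pressure; zero flow")
    return(list(RBF = 0, P_glom = P_ven, GFR = 0))
  }
  RBF <- dP / R_tot                            # L/min
  P_glom <- MAP - RBF * (re$R_preaff + re$R_aff)
  GFR <- re$K_f * max(P_glom - re$P_filt_offset, 0)
  list(RBF = RBF, P_glom = P_glom, GFR = GFR)
}

#' @keywords internal
clamp_fraction <- function(x, what) {
  if (x < 0.001 || x > 0.999) {
    warning("reabsorption fraction ", what, " clamped to (0.001, 0.999)")
    x <- min(max(x, 0.001), 0.999)
  }
  x
}

#' Tubular sodium and water handling
#'
#' Segment-wise fractional reabsorption (proximal, distal, collecting duct).
#' Angiotensin II stimulates proximal reabsorption, aldosterone stimulates
#' collecting-duct reabsorption, and RIHP above its set-point inhibits both
#' proximal and collecting-duct reabsorption (pressure natriuresis). Water
#' excretion follows sodium iso-osmotically with a corrective osmotic (ADH)
#' term that returns plasma sodium to its reference.
#'
#' @param GFR glomerular filtration rate (mL/min)
#' @param cNa plasma sodium concentration (mmol/L)
#' @param params `cr_params`
#' @param hormones list with normalized `ANGII` and `ALD` (baseline 1)
#' @param RIHP renal interstitial hydrostatic pressure (mmHg)
#' @return list: `U_Na` (mmol/min), `U_water` (mL/min), effective fractions,
#'   and `MD_delivery` (distal sodium delivery, mmol/min)
#' @export
tubular_sodium_handling <- function(GFR, cNa, params, hormones = NULL,
                                    RIHP = params$renal$RIHP0) {
  if (GFR < 0) stop("tubular_sodium_handling: GFR must be >= 0")
  re <- params$renal
  ang <- if (is.null(hormones)) 1 else hormones$ANGII
  ald <- if (is.null(hormones)) 1 else hormones$ALD
  dR <- RIHP - re$RIHP0
  eta_pt <- clamp_fraction(re$eta_pt * (1 + re$k_ang_pt * (ang - 1)) -
                             re$s_pn_pt * dR, "eta_pt")
  eta_dt <- clamp_fraction(re$eta_dt, "eta_dt")
  eta_cd <- clamp_fraction(re$eta_cd * (1 + re$k_ald_cd * (ald - 1)) -
                             re$s_pn_cd * dR, "eta_cd")
  load <- GFR * cNa / 1000                     # mmol/min
  MD <- load * (1 - eta_pt)
  U_Na <- MD * (1 - eta_dt) * (1 - eta_cd)
  U_water <- U_Na / cNa * 1000 *
    exp(re$k_osm * (cNa - params$fluid$cNa_ref) / params$fluid$cNa_ref)
  list(U_Na = U_Na, U_water = U_water, eta_pt = eta_pt, eta_dt = eta_dt,
       eta_cd = eta_cd, MD_delivery = MD)
}

#' Renin-angiotensin-aldosterone feedback
#'
#' Normalized hormone kinetics: renin secretion falls with glomerular pressure
#' and with macula-densa sodium delivery; angiotensin II tracks renin
#' (fast equilibrium); aldosterone follows angiotensin II with saturation.
#' All levels are 1 at the healthy baseline, so baseline derivatives vanish.
#'
#' @param hormones list with `PRA` and `ALD` states
#' @param params `cr_params` with computed setpoints
#' @param P_glom glomerular pressure (mmHg)
#' @param MD_delivery distal sodium delivery (mmol/min)
#' @return list with derivatives (per day) `dPRA`, `dALD` and the algebraic
#'   `ANGII` level
#' @export
raas_feedback <- function(hormones, params, P_glom, MD_delivery) {
  ho <- params$hormones; sp <- params$setpoints
  sec <- exp(-ho$k_renin_p * (P_glom / sp$P_glom0 - 1) -
               ho$k_renin_md * (MD_delivery / sp$MD0 - 1))
  sec <- min(max(sec, ho$renin_min), ho$renin_max)
  dPRA <- (sec - hormones$PRA) / ho$tau_renin
  ANGII <- hormones$PRA
  ald_target <- max(ANGII, 0)^ho$ald_exp
  dALD <- (ald_target - hormones$ALD) / ho$tau_ald
  list(dPRA = dPRA, dALD = dALD, ANGII = ANGII,
       renin_sec = sec, ald_target = ald_target)
}

#' Body-fluid compartment derivatives
#'
#' Water balance (net intake minus urine output) over the extracellular
#' compartment, and Starling transcapillary exchange between plasma and
#' interstitium: \eqn{J = K_{cap}[(P_{cap} - P_{if}) - \pi_d]} with an
#' interstitial compliance and a constant effective oncotic gradient
#' (anchored so the baseline flux is zero). Water and sodium are conserved
#' by construction.
#'
#' @param fluid list with `V_ecf`, `V_if`, `Na` states (mL, mL, mmol)
#' @param excretion result of [tubular_sodium_handling()]
#' @param params `cr_params` with computed setpoints
#' @param P_cap capillary interface pressure (mmHg)
#' @return list of per-day derivatives `dNa`, `dV_ecf`, `dV_if`
#' @export
fluid_compartments_rhs <- function(fluid, excretion, params, P_cap) {
  fl <- params$fluid; sp <- params$setpoints
  V_pl <- fluid$V_ecf - fluid$V_if
  P_if <- fl$P_if0 + (fluid$V_if - fl$V_if0) / fl$C_if
  pi_d <- sp$pi_d0
  J <- fl$K_cap * ((P_cap - P_if) - pi_d)      # mL/min into interstitium
  dNa <- fl$Na_intake - per_min_to_per_day(excretion$U_Na)
  dV_ecf <- sp$water_net_intake - per_min_to_per_day(excretion$U_water)
  dV_if <- per_min_to_per_day(J)
  list(dNa = dNa, dV_ecf = dV_ecf, dV_if = dV_if, J_cap = J, P_if = P_if)
}
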