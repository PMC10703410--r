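## Myocyte-geometry bookkeeping and the growth laws: series (length) growth
## driven by end-diastolic stress or stretch exceeding its set-point
## (irreversible), and parallel (diameter) growth driven bidirectionally by
## peak systolic stress.

#' Myocyte volume of a cylinder population
#'
#' \eqn{V = N \pi D^2 L / 4}.
#'
#' @param N_myo myocyte count
#' @param D_myo average diameter (um)
#' @param L_myo average length (um)
#' @return volume in cubic micrometres
#' @export
#' @examples
#' myocyte_volume(2, 10, 100) # 2 * pi * 2500
myocyte_volume <- function(N_myo, D_myo, L_myo) {
  stopifnot(N_myo > 0, D_myo > 0, L_myo > 0)
  N_myo * pi * D_myo^2 * L_myo / 4
}

#' Zero-pressure cavity volume after myocyte elongation
#'
#' \eqn{V_{lv,zero-p} = V_{lv,0} (1 + \Delta L / L_0)^3}: series sarcomere
#' addition inflates the unloaded cavity cubically.
#'
#' @param V_lv_0 unloaded cavity volume before remodeling (mL)
#' @param dL_myo myocyte elongation (um, >= 0)
#' @param L_myo_0 healthy myocyte length (um)
#' @return volume in mL
#' @export
zero_pressure_volume <- function(V_lv_0, dL_myo, L_myo_0) {
  if (any(dL_myo < 0)) stop("zero_pressure_volume: dL_myo must be >= 0")
  V_lv_0 * (1 + dL_myo / L_myo_0)^3
}

#' Myocyte elongation rate
#'
#' \eqn{d\Delta L/dt = \max(K_l (s/s_0 - 1), 0)} where the driving signal `s`
#' is the end-diastolic fiber stress (mode `"stress"`) or stretch (mode
#' `"strain"`); never negative, so elongation is irreversible. `K_l = 0`
#' disables the law. The rate saturates at `rate_max` (sarcomere addition is
#' biologically rate-limited), which bounds how fast the ventricle can
#' dilate however large the driving excess.
#'
#' @param mode `"stress"` or `"strain"`
#' @param K_l rate constant (um/day, >= 0)
#' @param sigma_f_ED end-diastolic fiber stress
#' @param lambda_f_ED end-diastolic stretch
#' @param sigma_f_ED_0 stress set-point
#' @param lambda_f_ED_0 stretch set-point
#' @param rate_max saturation rate (um/day)
#' @return elongation rate (um/day)
#' @export
elongation_rate <- function(mode, K_l, sigma_f_ED, lambda_f_ED,
                            sigma_f_ED_0, lambda_f_ED_0, rate_max = Inf) {
  mode <- match.arg(mode, c("stress", "strain"))
  if (K_l < 0) stop("elongation_rate: K_l must be >= 0")
  ratio <- if (mode == "stress") sigma_f_ED / sigma_f_ED_0
           else lambda_f_ED / lambda_f_ED_0
  min(max(K_l * (ratio - 1), 0), rate_max)
}

#' Myocyte diameter remodeling rate
#'
#' Wall thickening driven by peak systolic fiber stress relative to its
#' set-point; bidirectional (regression of hypertrophy is allowed).
#'
#' @param sigma_f_peak peak systolic fiber stress
#' @param sigma_f_peak_0 set-point
#' @param K_d rate constant (um/day, >= 0)
#' @return diameter change rate (um/day)
#' @export
diameter_remodeling_rate <- function(sigma_f_peak, sigma_f_peak_0, K_d) {
  if (K_d < 0) stop("diameter_remodeling_rate: K_d must be >= 0")
  K_d * (sigma_f_peak / sigma_f_peak_0 - 1)
}
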