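## Iso-strain two-component passive myocardium: myocytes and extracellular
## matrix in parallel share the same stretch; total stress is the
## area-fraction-weighted sum of the component stresses. Opt-in: the
## homogeneous single-stiffness law remains the default.

#' Construct an iso-strain composite stiffness description
#'
#' @param c_f_myo myocyte stiffness constant (> 0)
#' @param c_f_ecm ECM stiffness constant (> 0)
#' @param phi_myo myocyte area/volume fraction
#' @param phi_ecm ECM area/volume fraction (`phi_myo + phi_ecm` must be 1)
#' @param beta shared stress scale
#' @return object of class `cr_composite`
#' @export
#' @examples
#' comp <- composite_stiffness(11, 22, phi_myo = 0.7, phi_ecm = 0.3, beta = 1)
composite_stiffness <- function(c_f_myo, c_f_ecm, phi_myo, phi_ecm,
                                beta = default_parameters()$cardiac$beta) {
  comp <- structure(
    list(c_f_myo = c_f_myo, c_f_ecm = c_f_ecm,
         phi_myo = phi_myo, phi_ecm = phi_ecm, beta = beta),
    class = "cr_composite")
  validate_composite(comp)
  comp
}

#' @keywords internal
validate_composite <- function(comp) {
  if (!inherits(comp, "cr_composite")) stop("not a cr_composite object")
  with(comp, {
    if (!all(is.finite(c(c_f_myo, c_f_ecm, phi_myo, phi_ecm, beta)))) {
      stop("composite_stiffness: non-finite field")
    }
    if (c_f_myo <= 0 || c_f_ecm <= 0 || beta <= 0) {
      stop("composite_stiffness: stiffness and stress-scale constants must be > 0")
    }
    if (phi_myo < 0 || phi_ecm < 0 || abs(phi_myo + phi_ecm - 1) > 1e-10) {
      stop("composite_stiffness: fractions must be non-negative and sum to 1")
    }
  })
  invisible(comp)
}

#' Component stresses under the iso-strain contract
#'
#' Both components see the same stretch; each follows the exponential law with
#' its own stiffness constant.
#'
#' @param lambda_f fiber stretch (> 0); vectorized
#' @param comp a `cr_composite`
#' @return list with `myo` and `ecm` stress vectors
#' @export
component_stresses <- function(lambda_f, comp) {
  validate_composite(comp)
  list(myo = passive_fiber_stress(lambda_f, comp$beta, comp$c_f_myo),
       ecm = passive_fiber_stress(lambda_f, comp$beta, comp$c_f_ecm))
}

#' Composite passive stress
#'
#' Fraction-weighted sum of the component stresses; reduces exactly to the
#' homogeneous law when the two stiffness constants are equal.
#'
#' @inheritParams component_stresses
#' @return composite fiber stress; vectorized
#' @export
composite_passive_stress <- function(lambda_f, comp) {
  s <- component_stresses(lambda_f, comp)
  comp$phi_myo * s$myo + comp$phi_ecm * s$ecm
}

#' Increase the ECM (collagen) volume fraction
#'
#' Adds `delta_ecm` to the ECM area and to the total area by the same amount,
#' then renormalizes, so the myocyte fraction falls and the ECM fraction rises
#' while the fractions still sum to one. `delta_ecm` is expressed as a
#' fraction of the current total area.
#'
#' @param comp a `cr_composite`
#' @param delta_ecm added ECM area as a fraction of the current total (>= 0)
#' @return modified `cr_composite`
#' @export
#' @examples
#' apply_volume_fraction_change(
#'   composite_stiffness(11, 22, 0.8, 0.2, 1), delta_ecm = 0.1)
apply_volume_fraction_change <- function(comp, delta_ecm) {
  validate_composite(comp)
  if (!is.finite(delta_ecm) || delta_ecm < 0) {
    stop("apply_volume_fraction_change: delta_ecm must be >= 0")
  }
  total <- 1 + delta_ecm
  comp$phi_ecm <- (comp$phi_ecm + delta_ecm) / total
  comp$phi_myo <- comp$phi_myo / total
  validate_composite(comp)
  comp
}
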