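## One-fiber left-ventricle mechanics: passive and active fiber stress, the
## stretch-volume relation, the asymmetric activation signal, and the cavity
## pressure map. These are the scalar building blocks; the beat integrator in
## src/ evaluates the same relations in compiled code.

#' Passive fiber stress
#'
#' Exponential strain-stiffening law \eqn{\sigma_f = \beta (e^{c_f(\lambda_f - 1)} - 1)}.
#' Negative stress for \eqn{\lambda_f < 1} (compression) is admitted; no clamp.
#'
#' @param lambda_f fiber stretch (dimensionless, > 0)
#' @param beta stress scaling constant (same units as the returned stress)
#' @param c_f fiber stiffness constant (dimensionless, > 0)
#' @return fiber stress, vectorized over `lambda_f`
#' @export
#' @examples
#' passive_fiber_stress(1.05, beta = 1, c_f = 11) # e^0.55 - 1
passive_fiber_stress <- function(lambda_f, beta, c_f) {
  if (any(!is.finite(lambda_f)) || !is.finite(beta) || !is.finite(c_f)) {
    stop("passive_fiber_stress: non-finite input")
  }
  if (any(lambda_f <= 0) || beta <= 0 || c_f <= 0) {
    stop("passive_fiber_stress: lambda_f, beta and c_f must be > 0")
  }
  beta * (exp(c_f * (lambda_f - 1)) - 1)
}

#' Fiber stretch from chamber volume
#'
#' \eqn{\lambda_f = ((V_{lv} + V_w/3) / (V_{lv,0p} + V_w/3))^{1/3}}: the
#' thick-walled spherical kinematics linking cavity volume to mid-wall fiber
#' stretch. Equals 1 at the zero-pressure volume and is strictly increasing
#' in `V_lv`.
#'
#' @param V_lv pressurized chamber volume (mL)
#' @param V_w wall volume (mL)
#' @param V_lv_zero_p zero-pressure chamber volume (mL)
#' @return fiber stretch (dimensionless), vectorized over `V_lv`
#' @export
fiber_stretch_from_volume <- function(V_lv, V_w, V_lv_zero_p) {
  if (any(!is.finite(V_lv)) || !is.finite(V_w) || !is.finite(V_lv_zero_p)) {
    stop("fiber_stretch_from_volume: non-finite input")
  }
  if (any(V_lv <= 0) || V_w <= 0 || V_lv_zero_p <= 0) {
    stop("fiber_stretch_from_volume: volumes must be > 0")
  }
  ((V_lv + V_w / 3) / (V_lv_zero_p + V_w / 3))^(1 / 3)
}

#' Asymmetric activation signal
#'
#' Piecewise sinusoidal excitation: a sin-squared rise over `[0, t_r]`, a
#' cos-squared fall over `[t_r, t_r + t_f + dt_f]` (the fall extension `dt_f`
#' models slowed relaxation and delays the return to zero by exactly `dt_f`),
#' and zero from the end of relaxation to the end of the beat. Continuous
#' everywhere with values in \[0, 1\]; with `dt_f = 0` and `t_r = t_f` the
#' waveform is symmetric about its peak.
#'
#' @param t time since activation onset (s), in `[0, t_beat)`; vectorized
#' @param t_r rise duration (s)
#' @param t_f normal fall duration (s)
#' @param dt_f incremental fall extension (s, >= 0)
#' @param t_beat beat period (s)
#' @return activation level in \[0, 1\]
#' @export
#' @examples
#' activation_signal(0.17, t_r = 0.17, t_f = 0.25, dt_f = 0, t_beat = 60 / 70)
activation_signal <- function(t, t_r, t_f, dt_f, t_beat) {
  if (t_r <= 0 || t_f <= 0 || dt_f < 0 || t_r + t_f + dt_f >= t_beat) {
    stop("activation_signal: timing invariants violated ",
         "(need t_r, t_f > 0, dt_f >= 0, t_r + t_f + dt_f < t_beat)")
  }
  if (any(t < 0 | t >= t_beat)) {
    stop("activation_signal: t must lie in [0, t_beat)")
  }
  fall <- t_f + dt_f
  ifelse(t < t_r,
         sin(pi * t / (2 * t_r))^2,
         ifelse(t < t_r + fall,
                cos(pi * (t - t_r) / (2 * fall))^2,
                0))
}

#' Length-dependence of active stress
#'
#' Sigmoidal activation-length relation \eqn{f(l_s)}; saturates for long
#' sarcomeres and vanishes for very short ones (Frank-Starling behaviour).
#' Inputs outside the bracket \[1.4, 3.0\] um are clamped to the boundary with
#' a warning (transient solver excursions are tolerated rather than fatal).
#'
#' @param l_s sarcomere length (um); vectorized
#' @param l_sf0 sigmoid midpoint (um)
#' @param k_fsig sigmoid width (um)
#' @return activation factor in (0, 1)
#' @export
sarcomere_length_factor <- function(l_s, l_sf0 = 2.0, k_fsig = 0.15) {
  lo <- 1.4; hi <- 3.0
  if (any(l_s < lo | l_s > hi)) {
    warning("sarcomere length outside [", lo, ", ", hi, "] um; clamped")
    l_s <- pmin(pmax(l_s, lo), hi)
  }
  1 / (1 + exp(-(l_s - l_sf0) / k_fsig))
}

#' Force-velocity factor
#'
#' Hill hyperbola for shortening (`v_s > 0`), mild linear enhancement for
#' lengthening, capped at `h_len_max`.
#'
#' @param v_s sarcomere shortening velocity (um/s, positive = shortening)
#' @param v_max maximum unloaded shortening velocity (um/s)
#' @param c_v Hill curvature
#' @param k_len eccentric slope
#' @param h_len_max eccentric cap
#' @return force-velocity factor (>= 0); vectorized over `v_s`
#' @export
force_velocity_factor <- function(v_s, v_max = 14, c_v = 1.5, k_len = 0.5,
                                  h_len_max = 1.4) {
  vv <- v_s / v_max
  ifelse(v_s >= 0,
         pmax(0, (1 - vv)) / (1 + c_v * pmax(vv, 0)),
         pmin(1 + k_len * (-vv), h_len_max))
}

#' Active fiber stress
#'
#' Product form \eqn{\sigma_{active} = c\,\sigma_{ar}\, f(l_s)\, g(t_a)\, h(v_s)}:
#' linear in contractility, zero whenever the activation signal is zero.
#'
#' @param c intrinsic contractility (>= 0)
#' @param l_s sarcomere length (um)
#' @param v_s shortening velocity (um/s)
#' @param t_a time since activation onset (s)
#' @param params a `cr_params` object supplying \eqn{\sigma_{ar}} and the
#'   shapes of f, g, h
#' @return active fiber stress (mmHg)
#' @export
active_fiber_stress <- function(c, l_s, v_s, t_a, params = default_parameters()) {
  if (!is.finite(c) || c < 0) stop("active_fiber_stress: c must be >= 0")
  ca <- params$cardiac
  g <- activation_signal(t_a, ca$t_r, ca$t_f, ca$dt_f, ca$t_beat)
  c * ca$sigma_ar *
    sarcomere_length_factor(l_s, ca$l_sf0, ca$k_fsig) * g *
    force_velocity_factor(v_s, ca$v_max, ca$c_v, ca$k_len, ca$h_len_max)
}

#' LV cavity pressure from total fiber stress
#'
#' One-fiber geometry factor for a thick-walled chamber:
#' \eqn{P_{lv} = (\sigma_{tot}/3)\,\ln(1 + V_w / V_{lv})}. Zero when the total
#' fiber stress is zero, strictly increasing in stress at fixed geometry.
#'
#' @param sigma_total total (passive + active) fiber stress (mmHg)
#' @param V_lv chamber volume (mL)
#' @param V_w wall volume (mL)
#' @return cavity pressure (mmHg); vectorized
#' @export
lv_pressure_from_stress <- function(sigma_total, V_lv, V_w) {
  if (any(V_lv <= 0) || V_w <= 0) stop("lv_pressure_from_stress: volumes must be > 0")
  (sigma_total / 3) * log(1 + V_w / V_lv)
}

#' LV cavity pressure at an instant
#'
#' Convenience wrapper combining the stretch-volume relation, passive and
#' active stress, and the cavity-pressure map. The composite (myocyte + ECM)
#' passive law is used automatically when `params$cardiac$composite` is set.
#'
#' @param V_lv chamber volume (mL)
#' @param t_a time since activation onset (s)
#' @param v_s sarcomere shortening velocity (um/s)
#' @param params a `cr_params` object
#' @return list with `P_lv`, `lambda_f`, `sigma_passive`, `sigma_active`
#' @export
lv_pressure <- function(V_lv, t_a, v_s = 0, params = default_parameters()) {
  ca <- params$cardiac
  V0p <- current_V_lv0p(params)
  V_w <- current_V_w(params)
  lam <- fiber_stretch_from_volume(V_lv, V_w, V0p)
  sig_p <- if (is.null(ca$composite)) {
    passive_fiber_stress(lam, ca$beta, ca$c_f)
  } else {
    composite_passive_stress(lam, ca$composite)
  }
  sig_a <- active_fiber_stress(ca$c, ca$l_s0 * lam, v_s, t_a, params)
  list(P_lv = lv_pressure_from_stress(sig_p + sig_a, V_lv, V_w),
       lambda_f = lam, sigma_passive = sig_p, sigma_active = sig_a)
}
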