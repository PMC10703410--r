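## Scalar vascular-segment relations. The flow network itself is evaluated
## inside the compiled beat integrator (src/beat.cpp); these are the exposed
## building blocks.

#' Vascular segment pressure
#'
#' Linear compliance law \eqn{P = (V - V_0)/C}. Pressure may be negative when
#' the volume falls below the unstressed volume; the linear law is retained
#' without a floor.
#'
#' @param V current volume (mL); vectorized
#' @param V_0 unstressed (capacitance) volume (mL)
#' @param C compliance (mL/mmHg, > 0)
#' @return pressure in mmHg
#' @export
#' @examples
#' segment_pressure(3133.5, 3000, 26.7)  # 5 mmHg
segment_pressure <- function(V, V_0, C) {
  if (!is.finite(C) || C <= 0) stop("segment_pressure: compliance must be > 0")
  (V - V_0) / C
}
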