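## Deterministic synthetic fixtures with known ground truth, used by the
## metric-estimator and sensitivity tests.

#' Generate a synthetic fixture
#'
#' Kinds:
#' * `"monoexp"`: a monoexponential pressure decay `P = Pa exp(-t/tau) + Pb`
#'   with known `tau` (ms); attributes carry the truth.
#' * `"pv_loop"`: an idealized rounded-rectangle pressure-volume loop with
#'   known EDV/ESV.
#' * `"ishigami"`: the Ishigami test function and its analytic Sobol indices.
#'
#' @param kind fixture kind
#' @param seed RNG seed for any jitter (monoexp noise defaults to none)
#' @param tau_ms,Pa,Pb monoexponential truth (ms, mmHg, mmHg)
#' @param EDV,ESV loop truth (mL)
#' @param a,b Ishigami constants
#' @return a list with the data and a `truth` element
#' @export
generate_fixtures <- function(kind = c("monoexp", "pv_loop", "ishigami"),
                              seed = 1, tau_ms = 40, Pa = 80, Pb = 0,
                              EDV = 120, ESV = 48, a = 7, b = 0.1) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "monoexp") {
    t <- seq(0, max(0.2, 5 * tau_ms / 1000), by = 5e-4)
    P <- Pa * exp(-t / (tau_ms / 1000)) + Pb
    return(list(t = t, P = P, truth = list(tau_ms = tau_ms, Pa = Pa, Pb = Pb)))
  }
  if (kind == "pv_loop") {
    th <- seq(0, 2 * pi, length.out = 401)
    V <- (EDV + ESV) / 2 + (EDV - ESV) / 2 * cos(th)
    P <- 10 + 110 * pmax(sin(th), 0)
    return(list(V = V, P = P,
                truth = list(EDV = EDV, ESV = ESV,
                             EF = 100 * (EDV - ESV) / EDV)))
  }
  # ishigami: f = sin(x1) + a sin^2(x2) + b x3^4 sin(x1), x_i ~ U(-pi, pi)
  f <- function(X) {
    sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
  }
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  Vtot <- V1 + V2 + V13
  list(f = f,
       ranges = list(x1 = c(-pi, pi), x2 = c(-pi, pi), x3 = c(-pi, pi)),
       truth = list(S1 = c(V1 / Vtot, V2 / Vtot, 0),
                    ST = c((V1 + V13) / Vtot, V2 / Vtot, V13 / Vtot),
                    variance = Vtot))
}
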