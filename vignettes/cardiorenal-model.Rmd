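---
title: "The integrated cardiorenal model: formulation, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The integrated cardiorenal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the package simulates

`cardiorenal` couples three subsystems that operate on very different time
scales:

1. **Beat-resolved left-ventricular mechanics** (milliseconds to seconds): a
   one-fiber model in which mid-wall fiber stretch is a cube-root function of
   cavity volume, passive fiber stress follows an exponential
   strain-stiffening law \(\sigma_f = \beta(e^{c_f(\lambda_f-1)}-1)\), active
   stress is the product \(c\,\sigma_{ar} f(l_s)\,g(t)\,h(v_s)\), and cavity
   pressure follows from total wall stress through the thick-wall geometry
   factor \(\tfrac{\sigma}{3}\ln(1+V_w/V_{lv})\).
2. **A lumped systemic and pulmonary circulation** (seconds): four linear
   compliance segments (systemic arterial and venous, pulmonary arterial and
   venous), an elastance right ventricle sharing the LV activation signal,
   and smoothed-diode valves.
3. **Renal sodium/water homeostasis and neurohormonal feedback** (hours to
   days): glomerular filtration from series arteriolar resistances and an
   ultrafiltration coefficient, segment-wise tubular sodium reabsorption
   modulated by angiotensin II, aldosterone, and pressure natriuresis,
   Starling exchange between plasma and interstitium, whole-body flow
   autoregulation, and the renin-angiotensin-aldosterone system.

The three are coupled exactly as the physiology dictates: mean arterial and
venous pressures from the circulation drive renal perfusion and sodium
excretion; excretion sets blood volume; blood volume closes the loop back
into the circulation. Chronic states — heart failure with preserved or
reduced ejection fraction — *emerge* from this loop rather than being
imposed: a stiff or weak ventricle initially under-fills the arteries, the
kidney retains sodium and water, and filling pressures climb until sodium
balance is restored.

On top of the coupled model sit two *outward remodeling laws* for myocyte
elongation (series sarcomere addition): growth driven by end-diastolic fiber
**stress** or by end-diastolic fiber **stretch**, each relative to a
set-point taken from the healthy baseline, plus a bidirectional diameter
(wall-thickening) law driven by peak systolic stress. Myocyte elongation
inflates the unloaded cavity volume cubically,
\(V_{lv,0p} = V_{lv,0}(1+\Delta L/L_0)^3\), which is what turns sustained
growth into chamber dilatation and, eventually, a falling ejection fraction.

# Parameters

Where a parameter has an established literature value we use it directly and
never revisit it: fiber stiffness `c_f = 11`, contractility `c = 1`,
compliances `C_art = 1.5`, `C_ven = 26.7`, `C_art,pulm = 2.7`,
`C_ven,pulm = 22` mL/mmHg, venous unstressed volume 3.0 L, renal resistances
14/10/51 mmHg·min/L, ultrafiltration coefficient 4.0 mL/min/mmHg, fractional
proximal and collecting-duct sodium reabsorption 66% and 84%, and the renal
interstitial hydrostatic pressure (RIHP) set-point 9.7 mmHg.

The remaining constants — the active and passive stress scales, activation
timing, valve and peripheral resistances, unstressed volumes, baseline blood
volume, and the renal/neurohormonal gains — were fixed once so that the
healthy baseline reproduces textbook resting physiology: ejection fraction
near 60%, MAP near 93 mmHg, systolic/diastolic arterial pressure near
115/75 mmHg, cardiac output near 5.5 L/min, LVEDP near 10 mmHg, GFR near
100 mL/min, an isovolumic relaxation time of 80 ms, and sodium excretion
equal to a 150 mmol/day intake. This calibration is part of the model
definition; nothing in it is revisited per scenario. `default_parameters()`
is the single source of truth, and every scenario derives a perturbed copy
via `apply_mechanism()` / `induce_hypertension()` (whose ranges — stiffness
+0–75%, contractility −0–20%, dilatation +0–25%, fall-time extension
+0–130 ms, compliances and venous capacitance −0–50%, renal hypertension
composite — are the simulated-change ranges of the study design).

Three parameter families deserve comment:

* **Activation timing.** The excitation signal is a sin² rise over `t_r`
  followed by a cos² fall over `t_f + dt_f`; the fall extension `dt_f`
  models slowed relaxation and delays the end of relaxation by exactly
  `dt_f`. With `t_r = 0.17` s and `t_f = 0.148` s the baseline IVRT is
  80 ms. One consequence of this piecewise-sinusoidal form is that active
  stress ends with the cos² branch: pressure decay during isovolumic
  relaxation has no exponential tail of its own, so the ratio between IVRT
  and the fitted time constant tau is essentially fixed by the waveform
  (about 2.6 with the default estimator). Extreme relaxation indices that
  would require a long quasi-exponential tail (IVRT several times longer
  than the activation fall) are therefore outside what this activation
  model can produce; the package reports what the model actually yields.
* **Remodeling rates.** The elongation rate constants (`K_l_stress`,
  `K_l_strain`) and the saturation rate `dL_rate_max = 0.8` um/day are
  chosen so that a remodeling episode plays out over months, not days. The
  saturation reflects the biological rate limit on sarcomere addition and
  is load-bearing numerically: without it, the strain-driven law is
  effectively bistable (either the renal relief of filling pressure
  outruns growth and remodeling stalls, or growth outruns relief and the
  chamber dilates without bound). The two laws see driving signals of very
  different relative magnitude (stress excesses of tens of percent versus
  stretch excesses of a few percent), which is why the strain law uses a
  larger rate constant.
* **Renal/neurohormonal gains.** The pressure-natriuresis gains
  (`s_pn_pt`, `s_pn_cd`), the RIHP pressure sensitivities, and the RAAS
  gains set how tightly arterial pressure is defended and how strongly the
  hypertension induction raises MAP. They were chosen once for a stable,
  non-oscillatory closed loop with a hypertension response spanning tens
  of mmHg at full severity.

# Numerical scheme

The central engineering choice is **multirate integration**. The beat-level
ODE (seven states) is integrated by a fixed-step RK4 in compiled code
(default step 0.25 ms) and iterated beat-by-beat until the start-of-beat
state repeats within 0.01 mL — a periodic steady state. The slow states
(sodium pool, extracellular and interstitial volume, hormones,
autoregulated resistance, remodeling geometry) advance on an adaptive macro
step of up to 0.2 days using Heun's method, re-solving the beat loop to
periodicity at every stage evaluation (warm-started, so usually only a few
beats are needed).

Two slow modes are much faster than the rest and are handled by operator
splitting with exact exponential updates rather than by shrinking the macro
step: the first-order hormone kinetics (renin, aldosterone, autoregulation)
relax toward targets frozen over the step, and the transcapillary
plasma–interstitium exchange — the stiffest slow mode, because plasma is
nearly incompliant compared to the interstitium — is linearized in the
interstitial volume (compliance `1/C_if` plus the effective
plasma-pressure slope `solver$c_exch`) and relaxed exactly. Both updates
leave steady states bit-identical to the underlying ODE (zero flux, target
attained) and only approximate transients. Water is conserved exactly: the
exchange moves volume between plasma and interstitium, and the
extracellular pool changes only by intake minus excretion.

A `method = "lsoda"` mode advances the same slow right-hand side with
`deSolve::lsoda` as an independent verification of the adaptive scheme; the
test suite asserts agreement of settled states.

Settling is declared when LVEDP, MAP, and blood volume each change by less
than 0.1% over the final 5 simulated days. Degenerate inputs are handled
explicitly: valve flows use a smoothed diode (regularization scale
0.3 mmHg) so the right-hand side stays continuous; sarcomere lengths
outside the activation-length bracket clamp with a warning; modulated
reabsorption fractions clamp to (0.001, 0.999) with a warning;
non-positive renal perfusion returns zero flow with a warning rather than
an error.

End-diastole is located at mitral-valve closure with sub-sample
interpolation of the flow crossing (the systolic pressure rise is steep
enough that index quantization alone would alias LVEDP). IVRT is the
cyclic time from aortic closure to mitral opening. Tau is fitted over the
window from minimum dP/dt to mitral opening; the default is the
zero-asymptote monoexponential because, on the calibrated baseline, it
reproduces the normal clinical IVRT/tau pairing, while the three-parameter
variant (available via `asymptote = TRUE`) absorbs the cos² tail into a
much larger constant. Both are exact on noiseless monoexponential input.

# Sensitivity analysis

`sobol_study()` evaluates the settled LVEDP and EF over the eight mechanism
severities (seven single-parameter mechanisms plus the composite
hypertension severity), sampled uniformly over their simulated-change
ranges — uniform because the ranges are the only stated constraint. The
paired-matrix design has exactly `2N(1+p)` rows; first- and total-order
indices use the Azzini paired-difference estimator with percentile
bootstrap confidence intervals over the design pairs. Failed rows would be
excluded pairwise with their partners; the run aborts if more than 1% fail.
The full-scale design (`N = 2^9`, 9216 model evaluations of a 60-day
settle) is not a desk-scale computation; the test suite runs a reduced `N`
with a `surrogate = TRUE` solver configuration (coarser beat step, looser
macro-step control, shorter settle) that approximates settled outputs to
within a few percent and is labeled accordingly.

# What the simulator does and does not capture

The simulated conditions are those of the study design: constant heart
rate, resting state, fixed sodium and water intake, a single lumped LV
without regional heterogeneity, and an empty-atria circulation in which
the pulmonary and systemic venous segments play the atrial roles. Passing
tests therefore demonstrate internal consistency of the coupled
mechanism — stiffening raising filling pressure at preserved EF,
strain-mitigation by stiffness, the divergence of the two remodeling
laws — not fidelity to any individual patient. Known divergences of this
implementation, reported as measured:

* The relaxation extremes under maximal fall-time extension are bounded by
  the cos² activation form (see *Activation timing* above); the reported
  IVRT/tau at `dt_f = 130` ms are far smaller than values that would
  require supplementary sarcomere-kinetic machinery.
* Renally induced hypertension is volume-mediated; with flow
  autoregulation it converts retained volume into pressure, but settled
  cardiac output ends slightly above baseline rather than below it along
  the pure-hypertension axis.
* In deeply remodeled states the dilated ventricle needs little preload,
  so end-diastolic pressure can normalize while EF is severely reduced;
  late HFrEF states are therefore reached at low rather than high filling
  pressures along some trajectories.
* Stacked insults interact strongly: the combined-insult corner of the
  severity space (impaired contractility plus arterial stiffening plus
  severe hypertension) settles at far higher filling pressures than any
  single mechanism produces, because the pulmonary-sided congestion is
  invisible to the renal pressure-natriuresis signal. This inflates
  interaction variance in the global sensitivity study, so first-order
  Sobol indices are smaller — and total-order indices larger — than they
  would be in a more nearly additive model; rankings are the robust
  summary at reduced scale.

# Reproducing the headline numbers

`scripts/acceptance.R` (repository root) recomputes the settled baseline
relaxation indices, the maximal-slowing indices, the stiffening-alone
HFpEF state, and the two strain-law remodeling endpoints from scratch
against the installed package and writes them as JSON; see the README for
invocation.
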