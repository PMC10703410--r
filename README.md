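# cardiorenal

An integrated, beat-resolved heart + kidney simulator for studying how
heart failure with *preserved* ejection fraction (HFpEF) differs from heart
failure with *reduced* ejection fraction (HFrEF). It is aimed at
cardiovascular modelers and quantitative physiologists who want chronic
hemodynamic states — filling pressures, fluid status, remodeling — to
*emerge* from closed-loop physiology rather than be prescribed.

## The model in brief

Left-ventricular mechanics follow a one-fiber model: mid-wall fiber stretch
is tied to cavity volume by

λ_f = ((V_lv + V_w/3) / (V_lv,0p + V_w/3))^(1/3),

passive fiber stress follows the strain-stiffening law
σ_f = β·(e^{c_f (λ_f − 1)} − 1) (optionally an iso-strain myocyte/ECM
composite, σ_f = φ_myo σ_myo + φ_ecm σ_ecm), active stress is the product
c·σ_ar·f(l_s)·g(t)·h(v_s) with an asymmetric sin²/cos² activation signal
whose falling arm can be lengthened by Δt_f to model slowed relaxation, and
cavity pressure is (σ/3)·ln(1 + V_w/V_lv). The chamber ejects into a
four-segment lumped circulation (linear compliances, smoothed-diode
valves, elastance right ventricle). A reduced kidney closes the slow loop:
glomerular filtration from series arteriolar resistances, segment-wise
tubular sodium reabsorption modulated by angiotensin II, aldosterone, and
pressure natriuresis (RIHP relative to its set-point), Starling exchange
with the interstitium, and whole-body flow autoregulation. Blood volume —
and with it preload and congestion — is whatever sodium balance demands.

Outward remodeling is myocyte elongation ΔL driven by either end-diastolic
fiber **stress** or **stretch** above its healthy set-point
(dΔL/dt = max(K_l (s/s₀ − 1), 0), irreversible, rate-saturated), inflating
the unloaded cavity volume as V_lv,0p = V_lv,0 (1 + ΔL/L₀)³. A Sobol
variance-based sensitivity module (paired-matrix design, Azzini estimator,
bootstrap CIs) ranks eight pathophysiological mechanisms — myocardial
stiffening, impaired contractility, outward dilatation, slowed relaxation,
arterial/venous stiffening, reduced venous capacitance, and renally induced
hypertension — as drivers of LVEDP and EF.

## Worked example

```r
library(cardiorenal)

p <- default_parameters()

# 60-day settle with fiber stiffness +75% (severity 1 of its range),
# outward dilatation fixed at zero, remodeling off
stiff <- apply_mechanism(p, mechanism_spec("lv_stiffness", 1))
res <- run_settling(stiff, days = 60)
round(unlist(res$metrics[c("EF", "LVEDP", "MAP", "CO")]), 1)
#>    EF LVEDP   MAP    CO
#>  58.6  41.6  89.3   5.4
res$hf_state
#> [1] "HFpEF"
```

A 75% stiffer myocardium initially under-fills the arteries; the kidney
retains sodium and water until output is restored, and the settled state
has an end-diastolic pressure of ~42 mmHg (congestion, ≥ 20 mmHg) at a
preserved ejection fraction of ~59% — a heart failure state with preserved
ejection fraction produced by stiffening alone. The same pattern can be
explored for any mechanism combination, and
`run_remodeling_protocol(p, mechanism_spec("contractility", 0.75), "strain")`
runs the 1-year remodeling experiment in which the stretch-driven growth
law lets a weakened ventricle dilate into the reduced-EF range while a
stiffened one keeps its EF.

A thin command-line front end is installed under `inst/cli/cardiorenal`
(verbs `simulate`, `remodel`, `sobol`, `validate-config`) over YAML run
configurations.

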