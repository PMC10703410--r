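Package: cardiorenal
Title: Integrated Cardiorenal Simulation of Heart Failure with Preserved
    Ejection Fraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Beat-resolved one-fiber left-ventricle mechanics coupled to a
    lumped-parameter systemic and pulmonary circulation and a reduced model of
    renal sodium and water homeostasis with neurohormonal feedback. Provides
    declarative pathophysiological mechanism perturbations (myocardial
    stiffening, impaired contractility, slowed relaxation, vascular stiffening,
    reduced venous capacitance, renally induced hypertension), stress- versus
    strain-driven outward remodeling laws, an iso-strain myocyte/extracellular
    matrix composite stiffness model, per-beat hemodynamic metrics (ejection
    fraction, end-diastolic pressure, isovolumic relaxation time, tau), a
    heart-failure state classifier, and variance-based Sobol global sensitivity
    analysis with the Azzini estimator and bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
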