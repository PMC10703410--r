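# Shared, lazily computed simulation results. Several tests interrogate the
# same settled states and remodeling trajectories; computing each once keeps
# the suite fast without weakening any assertion.

.runs <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.runs[[key]])) .runs[[key]] <- force(expr)
  .runs[[key]]
}

baseline_params <- function() cached("params", compute_setpoints(default_parameters()))

baseline_beat <- function() cached("beat", {
  p <- baseline_params()
  run_beats(p)
})

baseline_metrics <- function() cached("metrics", {
  beat_metrics(baseline_beat(), baseline_params())
})

settle_mechanism <- function(mechanism, severity, days = 60) {
  key <- paste0("settle_", mechanism, "_", severity, "_", days)
  cached(key, {
    p <- apply_mechanism(baseline_params(), mechanism_spec(mechanism, severity))
    p$remodel$K_l <- 0; p$remodel$K_d <- 0
    suppressWarnings(run_simulation(p, days = days))
  })
}

settle_combo <- function(key, severities, days = 60) {
  cached(paste0("combo_", key), {
    specs <- lapply(names(severities), function(m)
      mechanism_spec(m, severities[[m]]))
    p <- apply_mechanisms(baseline_params(), specs)
    p$remodel$K_l <- 0; p$remodel$K_d <- 0
    suppressWarnings(run_simulation(p, days = days))
  })
}

remodeling_arm <- function(mechanism, severity, law) {
  key <- paste0("remodel_", mechanism, "_", severity, "_", law)
  cached(key, {
    suppressWarnings(run_remodeling_protocol(
      default_parameters(), mechanism_spec(mechanism, severity),
      law_mode = law))
  })
}

mechanism_sobol <- function() cached("sobol_study", {
  suppressWarnings(sobol_study(N = 2^4, seed = 11, days = 15,
                               replicates = 500, surrogate = TRUE))
})
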