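# Waveform-derived observables: EF, valve events, IVRT, tau, HF classifier,
# spherical pressure-stress-strain relations.

test_that("ejection fraction follows its definition on synthetic loops", {
  fx <- generate_fixtures("pv_loop", EDV = 120, ESV = 48)
  expect_equal(fx$truth$EF, 60)
  expect_equal(100 * (max(fx$V) - min(fx$V)) / max(fx$V), 60, tolerance = 1e-9)
  fx2 <- generate_fixtures("pv_loop", EDV = 100, ESV = 65)
  expect_equal(fx2$truth$EF, 35)   # reduced-EF range
})

test_that("tau estimator recovers noiseless monoexponentials exactly", {
  for (tau in c(25, 40, 220)) {
    for (Pb in c(0, 6)) {
      fx <- generate_fixtures("monoexp", tau_ms = tau, Pa = 80, Pb = Pb)
      est <- estimate_tau_decay(fx$t, fx$P, asymptote = TRUE)
      expect_equal(est, tau, tolerance = 1e-6)
    }
    # zero-asymptote variant exact when there is no asymptote
    fx0 <- generate_fixtures("monoexp", tau_ms = tau, Pa = 80, Pb = 0)
    expect_equal(estimate_tau_decay(fx0$t, fx0$P, asymptote = FALSE), tau,
                 tolerance = 1e-6)
  }
  fx <- generate_fixtures("monoexp")
  expect_error(estimate_tau_decay(rev(fx$t), rev(fx$P)), "decay")
})

test_that("IVRT equals the aortic-closure to mitral-opening separation", {
  # synthetic beat with valve events a known distance apart
  n <- 2000; dt <- 5e-4
  t <- (seq_len(n) - 1) * dt
  q_av <- ifelse(t > 0.05 & t < 0.30, 200, 0)
  q_mit <- ifelse(t > 0.60 & t < 0.90, 150, 0)
  W <- cbind(t = t, V_lv = 100 + 20 * sin(2 * pi * t), P_lv = 50 - 40 * t,
             P_sa = 90, P_sv = 4, P_pa = 15, P_pv = 9, P_rv = 10,
             q_mit = q_mit, q_av = q_av, lambda = 1.1, sigma_p = 30,
             sigma_a = 0, V_rv = 100)
  beat <- list(waveform = W, converged = TRUE)
  expect_equal(estimate_ivrt(beat), 300, tolerance = 1)
  ev <- valve_events(W)
  expect_false(is.na(ev$t_avc)); expect_false(is.na(ev$t_mvo))
})

test_that("IVRT and tau increase monotonically with the relaxation extension", {
  p <- baseline_params()
  vals <- sapply(c(0, 0.05, 0.10, 0.13), function(dtf) {
    pp <- set_parameters(p, list("cardiac.dt_f" = dtf))
    b <- run_beats(pp)
    c(estimate_ivrt(b), estimate_tau(b))
  })
  expect_true(all(diff(vals[1, ]) > 0))
  expect_true(all(diff(vals[2, ]) > 0))
})

test_that("HF classification partitions the EF-LVEDP plane", {
  expect_equal(classify_hf_state(55, 25), "HFpEF")
  expect_equal(classify_hf_state(45, 25), "HF-mEF")
  expect_equal(classify_hf_state(60, 12), "non-HF")
  expect_equal(classify_hf_state(35, 22), "HFrEF")
  # boundary ties: LVEDP 20 is HF; EF 50 preserved; EF 40 midrange
  expect_equal(classify_hf_state(50, 20), "HFpEF")
  expect_equal(classify_hf_state(40, 20), "HF-mEF")
  expect_equal(classify_hf_state(39.999, 20), "HFrEF")
  expect_equal(classify_hf_state(70, 19.999), "non-HF")
  # exhaustive and mutually exclusive over a grid
  grid <- expand.grid(EF = seq(5, 95, by = 2.5), LVEDP = seq(2, 50, by = 2))
  lab <- classify_hf_state(grid$EF, grid$LVEDP)
  expect_true(all(lab %in% c("HFpEF", "HF-mEF", "HFrEF", "non-HF")))
  expect_equal(length(lab), nrow(grid))
  expect_error(classify_hf_state(NA, 10), "finite")
})

test_that("spherical relations: stress linear in pressure, strain log-linear and 1/c_f", {
  P <- 10 * 2^(seq(0, 3.4, by = 0.2))   # over a decade of pressures
  r <- spherical_strain_relation(P, c_f = 11)
  expect_equal(r$stress / P, rep(r$stress[1] / P[1], length(P)),
               tolerance = 1e-12)
  # log-linearity: R^2 of strain on log P approaches 1
  fit <- summary(lm(r$strain ~ log(P)))
  expect_gt(fit$r.squared, 0.995)
  # doubling stiffness halves strain (asymptotically, high-pressure regime)
  r2 <- spherical_strain_relation(P, c_f = 22)
  ratio <- r2$strain[length(P)] / r$strain[length(P)]
  expect_equal(ratio, 0.5, tolerance = 0.02)
  # numerical cross-check against inversion of the passive law on the sphere
  beta <- 6.5; L0 <- log(1 + 200 / 120)
  lam_num <- vapply(P, function(pp) {
    uniroot(function(l) passive_fiber_stress(l, beta, 11) - 3 * pp / L0,
            c(1 + 1e-9, 2))$root
  }, 0)
  expect_equal(r$strain, lam_num - 1, tolerance = 1e-3)
})

test_that("beat metrics report a coherent baseline summary", {
  m <- baseline_metrics()
  expect_gt(m$EF, 0); expect_lt(m$EF, 100)
  expect_gt(m$EDV, m$ESV)
  expect_gt(m$IVRT, 0); expect_gt(m$tau, 0)
  expect_equal(m$SV, m$EDV - m$ESV)
  expect_equal(m$pulse_pressure, m$SBP - m$DBP)
  expect_gt(m$E_es, 0); expect_gt(m$E_a, 0)
  expect_gt(m$stressed_volume, 0)
})
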