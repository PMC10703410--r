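# Renal hemodynamics, tubular sodium handling, fluid compartments, RAAS.

test_that("glomerular filtration responds with the expected signs", {
  p <- baseline_params()
  sp <- p$setpoints
  rh <- renal_hemodynamics(sp$MAP0, p, P_ven = sp$P_ven0)
  expect_gt(rh$GFR, 80); expect_lt(rh$GFR, 130)   # normal range
  expect_gt(rh$RBF, 0.8); expect_lt(rh$RBF, 1.5)  # L/min
  # reduced ultrafiltration coefficient lowers GFR at fixed pressures
  p2 <- p; p2$renal$K_f <- p$renal$K_f * 0.6
  expect_lt(renal_hemodynamics(sp$MAP0, p2, P_ven = sp$P_ven0)$GFR, rh$GFR)
  # raised afferent resistance lowers glomerular pressure
  p3 <- p; p3$renal$R_aff <- p$renal$R_aff * 2
  expect_lt(renal_hemodynamics(sp$MAP0, p3, P_ven = sp$P_ven0)$P_glom,
            rh$P_glom)
  expect_warning(renal_hemodynamics(3, p, P_ven = 4), "perfusion")
})

test_that("sodium excretion balances intake at the baseline steady state", {
  p <- baseline_params()
  sp <- p$setpoints
  rh <- renal_hemodynamics(sp$MAP0, p, P_ven = sp$P_ven0)
  tub <- tubular_sodium_handling(rh$GFR, p$fluid$cNa_ref, p,
                                 hormones = list(ANGII = 1, ALD = 1),
                                 RIHP = p$renal$RIHP0)
  expect_equal(tub$U_Na * 1440, p$fluid$Na_intake, tolerance = 1e-6)
  expect_equal(tub$U_water * 1440, sp$water_net_intake, tolerance = 1e-6)
})

test_that("pressure natriuresis raises excretion when RIHP exceeds its set-point", {
  p <- baseline_params()
  rh <- renal_hemodynamics(p$setpoints$MAP0, p, P_ven = p$setpoints$P_ven0)
  horm <- list(ANGII = 1, ALD = 1)
  u0 <- tubular_sodium_handling(rh$GFR, 140, p, horm, RIHP = p$renal$RIHP0)
  rihp_up <- renal_interstitial_pressure(p$setpoints$MAP0 + 10,
                                         p$setpoints$P_ven0, p)
  expect_gt(rihp_up, p$renal$RIHP0)
  u1 <- tubular_sodium_handling(rh$GFR, 140, p, horm, RIHP = rihp_up)
  expect_gt(u1$U_Na, u0$U_Na)
  # hormone modulation: ANG II and aldosterone reduce excretion
  u2 <- tubular_sodium_handling(rh$GFR, 140, p,
                                list(ANGII = 1.5, ALD = 1.5),
                                RIHP = p$renal$RIHP0)
  expect_lt(u2$U_Na, u0$U_Na)
  # extreme modulation clamps rather than producing nonsense fractions
  expect_warning(
    tubular_sodium_handling(rh$GFR, 140, p, list(ANGII = 40, ALD = 1),
                            RIHP = p$renal$RIHP0), "clamped")
})

test_that("raised tubular reabsorption causes transient retention and BV rise", {
  p <- baseline_params()
  p2 <- p
  p2$renal$eta_pt <- p$renal$eta_pt * 1.08
  p2$renal$eta_cd <- p$renal$eta_cd * 1.08
  sim <- suppressWarnings(run_simulation(p2, days = 10))
  expect_gt(tail(sim$trajectory$BV, 1), p$blood$BV0)
})

test_that("baseline slow state is an equilibrium of the coupled system", {
  p <- baseline_params()
  y <- cardiorenal:::initial_slow_state(p)
  cache <- new.env(); cache$fast_state <- p$setpoints$fast_state0
  ev <- cardiorenal:::slow_derivs(y, p, cache)
  d <- ev$deriv
  # per-day derivatives are negligible against the pool sizes
  expect_lt(abs(d[["Na"]]) / y[["Na"]], 1e-4)
  expect_lt(abs(d[["V_ecf"]]) / y[["V_ecf"]], 1e-4)
  expect_lt(abs(d[["V_if"]]) / y[["V_if"]], 1e-4)
  expect_lt(abs(d[["PRA"]]), 1e-2)
  expect_lt(abs(d[["ALD"]]), 1e-2)
  expect_identical(unname(d[["dL"]]), 0)
})

test_that("water and sodium are conserved over a closed interval", {
  p <- baseline_params()
  p2 <- apply_mechanism(p, mechanism_spec("lv_stiffness", 0.6))
  p2$remodel$K_l <- 0; p2$remodel$K_d <- 0
  sim <- suppressWarnings(run_simulation(p2, days = 15, record_dt = 0.5))
  tr <- sim$trajectory
  # the extracellular pool only changes through intake minus excretion, and
  # plasma + interstitium + red cells account for all of it at every sample
  V_ecf <- sim$slow_state[["V_ecf"]]
  V_pl <- sim$slow_state[["V_ecf"]] - sim$slow_state[["V_if"]]
  expect_equal(tail(tr$BV, 1), V_pl + p$blood$V_rbc, tolerance = 1e-6)
  # plasma sodium is held at its reference by the osmotic control
  expect_equal(tail(tr$cNa, 1), p$fluid$cNa_ref, tolerance = 0.01)
})

test_that("renin rises when renal perfusion falls and hormones stay positive", {
  p <- baseline_params()
  rh_lo <- renal_hemodynamics(p$setpoints$MAP0 - 15, p,
                              P_ven = p$setpoints$P_ven0)
  ra <- raas_feedback(list(PRA = 1, ALD = 1), p, rh_lo$P_glom,
                      p$setpoints$MD0)
  expect_gt(ra$dPRA, 0)   # secretion above current level
  # hormone levels stay positive across the full mechanism suite
  for (m in c("lv_stiffness", "contractility", "hypertension",
              "venous_capacitance")) {
    sim <- settle_mechanism(m, 1)
    expect_true(all(sim$trajectory$ANGII > 0))
  }
})
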