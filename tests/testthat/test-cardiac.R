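# One-fiber mechanics: passive law, stretch-volume kinematics, activation
# signal, active stress, cavity pressure.

test_that("passive fiber stress follows the exponential law", {
  expect_equal(passive_fiber_stress(1, beta = 3.7, c_f = 11), 0)
  # direct evaluation, c_f at its literature baseline
  expect_equal(passive_fiber_stress(1.05, beta = 1, c_f = 11),
               exp(0.55) - 1, tolerance = 1e-12)
  expect_equal(passive_fiber_stress(1.05, beta = 1, c_f = 11), 0.7333,
               tolerance = 1e-4)
  # +75% stiffness case
  expect_equal(passive_fiber_stress(1.05, beta = 1, c_f = 11 * 1.75),
               exp(0.9625) - 1, tolerance = 1e-12)
  expect_equal(passive_fiber_stress(1.05, beta = 1, c_f = 11 * 1.75), 1.6182,
               tolerance = 1e-3)
  # strictly increasing in stretch and stiffness above lambda = 1
  lam <- seq(1.01, 1.3, by = 0.01)
  s <- passive_fiber_stress(lam, 6.5, 11)
  expect_true(all(diff(s) > 0))
  expect_true(all(passive_fiber_stress(lam, 6.5, 19.25) > s))
  # compression admitted, not clamped
  expect_lt(passive_fiber_stress(0.95, 6.5, 11), 0)
  expect_error(passive_fiber_stress(NaN, 6.5, 11), "non-finite")
})

test_that("fiber stretch from volume matches the cube-root relation", {
  expect_equal(fiber_stretch_from_volume(60, 200, 60), 1)
  expect_equal(fiber_stretch_from_volume(120, 200, 60),
               ((120 + 200 / 3) / (60 + 200 / 3))^(1 / 3), tolerance = 1e-12)
  expect_equal(fiber_stretch_from_volume(120, 200, 60), 1.1380,
               tolerance = 1e-4)
  V <- seq(40, 200, by = 5)
  expect_true(all(diff(fiber_stretch_from_volume(V, 200, 60)) > 0))
  expect_error(fiber_stretch_from_volume(-5, 200, 60), "volumes")
})

test_that("activation signal is continuous, bounded, and shifts by dt_f", {
  t_beat <- 60 / 70
  g <- function(t, dt_f = 0, t_r = 0.17, t_f = 0.15) {
    activation_signal(t, t_r, t_f, dt_f, t_beat)
  }
  expect_equal(g(0), 0)
  expect_equal(g(0.17), 1)          # peak at end of rise
  tt <- seq(0, t_beat - 1e-6, length.out = 4001)
  gg <- g(tt)
  expect_true(all(gg >= 0 & gg <= 1))
  # pointwise continuity at the branch boundaries
  eps <- 1e-9
  for (tb in c(0.17, 0.17 + 0.15)) {
    expect_equal(g(tb - eps), g(tb + eps), tolerance = 1e-6)
  }
  # symmetric about the peak when rise and fall are equal and dt_f = 0
  gs <- function(t) activation_signal(t, 0.16, 0.16, 0, t_beat)
  for (d in c(0.02, 0.07, 0.12)) {
    expect_equal(gs(0.16 - d), gs(0.16 + d), tolerance = 1e-12)
  }
  # the end of relaxation moves by exactly dt_f
  end0 <- 0.17 + 0.15
  expect_equal(g(end0 - 1e-6), 0, tolerance = 1e-9)
  expect_gt(g(end0 + 0.05, dt_f = 0.13), 0)
  expect_equal(g(end0 + 0.13 - 1e-6, dt_f = 0.13), 0, tolerance = 1e-9)
  expect_equal(g(end0 + 0.13 + 1e-6, dt_f = 0.13), 0)
  expect_error(g(-0.1), "t must lie")
  expect_error(activation_signal(0.1, 0.5, 0.5, 0, 60 / 70), "timing")
})

test_that("active stress is multiplicative and linear in contractility", {
  p <- default_parameters()
  s1 <- active_fiber_stress(1, l_s = 2.1, v_s = 2, t_a = 0.2, params = p)
  expect_gt(s1, 0)
  expect_equal(active_fiber_stress(0, 2.1, 2, 0.2, p), 0)
  expect_equal(active_fiber_stress(0.5, 2.1, 2, 0.2, p), s1 / 2)
  expect_equal(active_fiber_stress(2, 2.1, 2, 0.2, p), 2 * s1)
  # zero whenever the activation signal is zero (late diastole)
  expect_equal(active_fiber_stress(1, 2.1, 2,
                                   p$cardiac$t_r + p$cardiac$t_f + 1e-3, p), 0)
  # out-of-bracket sarcomere length clamps with a warning, does not abort
  expect_warning(active_fiber_stress(1, 3.5, 0, 0.2, p), "clamped")
})

test_that("cavity pressure is zero when unloaded and monotone in stress", {
  expect_equal(lv_pressure_from_stress(0, 60, 200), 0)
  sig <- seq(0, 300, by = 10)
  expect_true(all(diff(lv_pressure_from_stress(sig, 100, 200)) > 0))
  p <- default_parameters()
  # unloaded state: at V = V_lv0 in diastole the passive stress vanishes
  res <- lv_pressure(p$cardiac$V_lv0, t_a = p$cardiac$t_beat - 1e-3, params = p)
  expect_equal(res$P_lv, 0, tolerance = 1e-10)
  expect_equal(res$lambda_f, 1)
})

test_that("the end-diastolic pressure-volume relation is monotone and c_f shifts it up", {
  p <- default_parameters()
  ta <- p$cardiac$t_beat - 1e-3           # diastole: no active stress
  V <- seq(80, 180, by = 10)
  edp <- vapply(V, function(v) lv_pressure(v, ta, params = p)$P_lv, 0)
  expect_true(all(diff(edp) > 0))
  p2 <- set_parameters(p, list("cardiac.c_f" = 11 * 1.6))
  edp2 <- vapply(V, function(v) lv_pressure(v, ta, params = p2)$P_lv, 0)
  expect_true(all(edp2 > edp))
})

test_that("baseline beat loop closes into a normal pressure-volume loop", {
  b <- baseline_beat()
  expect_true(b$converged)
  m <- baseline_metrics()
  expect_gt(m$EF, 50)
  expect_lt(m$LVEDP, 20)
  expect_gt(m$MAP, 80); expect_lt(m$MAP, 110)
  expect_gt(m$EDV, m$ESV)
  # loop closure: end state repeats within the solver tolerance
  W <- b$waveform
  expect_lt(abs(W[1, "V_lv"] - W[nrow(W), "V_lv"]),
            2 * baseline_params()$solver$beat_tol + 0.05)
})
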