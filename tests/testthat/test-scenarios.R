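# Mechanism perturbations and the settling / remodeling protocols.

test_that("mechanism application scales exactly the documented parameters", {
  p <- default_parameters()
  # identity at severity zero for every mechanism
  for (m in mechanism_names()) {
    expect_identical(apply_mechanism(p, mechanism_spec(m, 0)), p)
  }
  expect_equal(apply_mechanism(p, mechanism_spec("lv_stiffness", 1))$cardiac$c_f,
               11 * 1.75)
  expect_equal(apply_mechanism(p, mechanism_spec("contractility", 1))$cardiac$c,
               0.8)
  expect_equal(
    apply_mechanism(p, mechanism_spec("outward_dilatation", 1))$remodel$dL,
    0.25 * p$remodel$L_myo0)
  expect_equal(
    apply_mechanism(p, mechanism_spec("slowed_relaxation", 1))$cardiac$dt_f,
    0.130)
  expect_equal(
    apply_mechanism(p, mechanism_spec("venous_capacitance", 0.5))$circ$V0_sv,
    3000 * 0.75)
  expect_equal(
    apply_mechanism(p, mechanism_spec("arterial_compliance", 1))$circ$C_sa,
    0.75)
  expect_error(mechanism_spec("lv_stiffness", 1.2), "severity")
  expect_error(mechanism_spec("not_a_mechanism", 0.5))
})

test_that("hypertension induction hits the published endpoint values", {
  p <- default_parameters()
  h0 <- induce_hypertension(p, 0)
  expect_identical(h0$renal, p$renal)
  h1 <- induce_hypertension(p, 1)
  expect_equal(h1$renal$R_preaff, 25.2)
  expect_equal(h1$renal$R_aff, 18)
  expect_equal(h1$renal$R_eff, 91.8)
  expect_equal(h1$renal$K_f, 2.4)
  expect_equal(h1$renal$eta_pt, 0.7128)
  expect_equal(h1$renal$eta_cd, 0.9072)
  expect_equal(h1$renal$RIHP0, 10.476)
})

test_that("distinct mechanisms commute", {
  p <- default_parameters()
  a <- mechanism_spec("lv_stiffness", 0.7)
  b <- mechanism_spec("hypertension", 0.4)
  cc <- mechanism_spec("venous_capacitance", 0.6)
  expect_identical(apply_mechanisms(p, list(a, b, cc)),
                   apply_mechanisms(p, list(cc, b, a)))
})

test_that("settled arterial pressure rises monotonically with hypertension severity", {
  maps <- vapply(c(0, 0.5, 1), function(s) {
    if (s == 0) return(baseline_params()$setpoints$MAP0)
    settle_mechanism("hypertension", s)$final$MAP
  }, 0)
  expect_true(all(diff(maps) > 0))
})

test_that("baseline settling stays healthy and stiffening alone produces HFpEF", {
  p <- baseline_params()
  base <- settle_mechanism("arterial_compliance", 0)   # baseline run
  expect_true(base$settled)
  expect_equal(classify_hf_state(base$final$EF, base$final$LVEDP), "non-HF")
  stiff <- settle_mechanism("lv_stiffness", 1)         # c_f +75%, dL = 0
  expect_true(stiff$settled)
  expect_equal(classify_hf_state(stiff$final$EF, stiff$final$LVEDP), "HFpEF")
})

test_that("combined contractility, arterial stiffening and hypertension leave the preserved-EF range", {
  # with normal stiffness, stacking the systolic/vascular/renal insults drives
  # EF below the preserved range at elevated filling pressure (never HFpEF)
  sim <- settle_combo("mEF", list(contractility = 1, arterial_compliance = 1,
                                  hypertension = 1))
  expect_lt(sim$final$EF, 50)
  expect_gte(sim$final$LVEDP, 20)
  expect_false(classify_hf_state(sim$final$EF, sim$final$LVEDP) == "HFpEF")
})

test_that("worsening insults raise LVEDP, IFV and end-diastolic stress, and depress CO", {
  base <- settle_mechanism("arterial_compliance", 0)
  for (m in c("lv_stiffness", "contractility", "arterial_compliance")) {
    half <- settle_mechanism(m, 0.5); full <- settle_mechanism(m, 1)
    expect_true(base$final$LVEDP < half$final$LVEDP &&
                  half$final$LVEDP < full$final$LVEDP, label = m)
    expect_gt(tail(full$trajectory$IFV, 1), tail(base$trajectory$IFV, 1))
    expect_gt(full$final$sigma_f_ED, base$final$sigma_f_ED)
    expect_lte(full$final$CO, base$final$CO + 0.02)
  }
  htn <- settle_mechanism("hypertension", 1)
  expect_gt(htn$final$LVEDP, base$final$LVEDP)
  expect_gt(tail(htn$trajectory$IFV, 1), tail(base$trajectory$IFV, 1))
  expect_gt(htn$final$sigma_f_ED, base$final$sigma_f_ED)
})

test_that("added stiffness mitigates the strain rise from other insults", {
  contr <- settle_mechanism("contractility", 1)
  both <- settle_combo("contr_stiff",
                       list(contractility = 1, lv_stiffness = 0.8))
  base <- settle_mechanism("arterial_compliance", 0)
  # contractility loss raises end-diastolic stretch...
  expect_gt(contr$final$lambda_f_ED, base$final$lambda_f_ED)
  # ...and stiffening pulls it back down while stress keeps rising
  expect_lt(both$final$lambda_f_ED, contr$final$lambda_f_ED)
  expect_gt(both$final$sigma_f_ED, contr$final$sigma_f_ED)
})

test_that("increasing any single insult never reverts heart failure", {
  # monotone classification: once the HF side is reached at lower severity,
  # higher severity stays on the HF side
  rank_hf <- function(sim) as.integer(sim$final$LVEDP >= 20)
  for (m in c("lv_stiffness", "hypertension")) {
    r <- vapply(c(0.5, 1), function(s) rank_hf(settle_mechanism(m, s)),
                integer(1))
    expect_true(all(diff(r) >= 0), label = m)
  }
})

test_that("remodeling laws diverge for stiffening but agree for contractility loss", {
  stiff_strain <- remodeling_arm("lv_stiffness", 0.8, "strain")
  stiff_stress <- remodeling_arm("lv_stiffness", 0.8, "stress")
  contr_strain <- remodeling_arm("contractility", 0.75, "strain")
  # strain law: stiffening keeps EF preserved at elevated filling pressure
  expect_gte(stiff_strain$final$EF, 50)
  expect_gte(stiff_strain$final$LVEDP, 20)
  # stress law: the same insult drives progressive EF decline
  tr <- subset(stiff_stress$trajectory, phase == "remodeling")
  expect_lt(stiff_stress$final$EF, 45)
  expect_lt(min(tr$EF), tr$EF[1] - 5)
  # contractility loss decays EF under the strain law too
  expect_lte(contr_strain$final$EF, 40)
  # divergence traces back to myocyte elongation
  expect_lt(tail(subset(stiff_strain$trajectory,
                        phase == "remodeling")$dL, 1), 2)
  expect_gt(tail(tr$dL, 1), 10)
})
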