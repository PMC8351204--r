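test_that("exposure conversion multiplies by body weight and rejects non-positives", {
  expect_equal(convert_exposure(0.35, 60), 21)
  expect_equal(convert_exposure(1.0, 70), 70)
  expect_error(convert_exposure(0.35, 0), "positive")
  expect_error(convert_exposure(-1, 60), "positive")
})

test_that("cohort-of-concern rules fire on metals and polyhalogenated cores", {
  # organic sodium salt: counterion dropped via largest-fragment convention
  salt <- coc_check("[Na+].[O-]S(=O)(=O)c1cccc2ccccc12")
  expect_false(salt$is_coc)

  lead <- coc_check("CC[Pb](CC)(CC)CC")
  expect_true(lead$is_coc)
  expect_match(lead$group, "metal")

  tcdd <- coc_check("Clc1cc2Oc3cc(Cl)c(Cl)cc3Oc2cc1Cl")
  expect_true(tcdd$is_coc)
  expect_match(tcdd$group, "dibenzodioxin")

  pcb <- coc_check("Clc1ccc(-c2ccc(Cl)c(Cl)c2)cc1Cl")
  expect_true(pcb$is_coc)
  expect_match(pcb$group, "biphenyl")

  # mono-halogenated biphenyl is not "polyhalogenated"
  expect_false(coc_check("Clc1ccc(-c2ccccc2)cc1")$is_coc)
  # unhalogenated dibenzofuran is not in the cohort
  expect_false(coc_check("c1ccc2c(c1)oc1ccccc12")$is_coc)
})

test_that("organophosphate detection matches phosphate/phosphorothioate esters", {
  expect_false(is_organophosphate("[Na+].[O-]S(=O)(=O)c1cccc2ccccc12"))
  expect_true(is_organophosphate("CCOP(=S)(OCC)Oc1ccc(cc1)[N+](=O)[O-]"))
  expect_true(is_organophosphate("COP(=O)(OC)OC"))
  expect_false(is_organophosphate("c1ccccc1"))
})

test_that("the worked food-contact example passes at the Class III node", {
  v <- ttc_evaluate("[Na+].[O-]S(=O)(=O)c1cccc2ccccc12", "III",
                    exposure = 0.35, exposure_unit = "ug_per_kg_bw_day",
                    body_weight_kg = 60, cramer_warning = TRUE)
  expect_equal(v$outcome, "pass")
  expect_equal(v$exposure_per_person, 21)
  expect_equal(v$threshold_applied, 90)
  expect_equal(v$fired_node, "Q9 Cramer III")
  expect_true(v$cramer_warning)
  expect_gt(nrow(v$trace), 0)
  expect_match(v$trace$question[1], "Q1")
  expect_equal(v$trace$answer[nrow(v$trace)], "pass")
})

test_that("cohort-of-concern compounds fail at Q1 independent of exposure", {
  for (expo in c(1e-6, 1, 1e9)) {
    v <- ttc_evaluate("CC[Pb](CC)(CC)CC", "I", exposure = expo,
                      exposure_unit = "ug_per_person_day")
    expect_equal(v$outcome, "fail")
    expect_equal(v$fired_node, "Q1 COC")
    expect_true(is.na(v$threshold_applied))
  }
})

test_that("threshold comparison is strict and monotone in exposure", {
  at <- ttc_evaluate("c1ccccc1", "III", exposure = 90,
                     exposure_unit = "ug_per_person_day")
  expect_equal(at$outcome, "fail")  # exposure equal to threshold fails
  below <- ttc_evaluate("c1ccccc1", "III", exposure = 89.999,
                        exposure_unit = "ug_per_person_day")
  expect_equal(below$outcome, "pass")

  # pass at e implies pass at every lower exposure
  exposures <- c(1, 10, 50, 89, 91, 200)
  outcomes <- vapply(exposures, function(e) {
    ttc_evaluate("c1ccccc1", "III", exposure = e,
                 exposure_unit = "ug_per_person_day")$outcome
  }, character(1))
  expect_equal(outcomes, c("pass", "pass", "pass", "pass", "fail", "fail"))
})

test_that("organophosphates branch to their own threshold at Q6", {
  op <- "CCOP(=S)(OCC)Oc1ccc(cc1)[N+](=O)[O-]"
  v <- ttc_evaluate(op, "III", exposure = 10, exposure_unit = "ug_per_person_day")
  expect_equal(v$fired_node, "Q6 organophosphate")
  expect_equal(v$threshold_applied, 18)
  expect_equal(v$outcome, "pass")
  v2 <- ttc_evaluate(op, "III", exposure = 30, exposure_unit = "ug_per_person_day")
  expect_equal(v2$outcome, "fail")
})

test_that("every evaluation reaches a terminal node with a non-empty trace", {
  cases <- list(
    list(smiles = "CCO", class = "I", e = 1000),
    list(smiles = "CC[Pb](CC)(CC)CC", class = "II", e = 5),
    list(smiles = "COP(=O)(OC)OC", class = "III", e = 100),
    list(smiles = NA, class = "III", e = 5))
  for (cs in cases) {
    v <- ttc_evaluate(cs$smiles, cs$class, exposure = cs$e,
                      exposure_unit = "ug_per_person_day")
    expect_gt(nrow(v$trace), 0)
    expect_true(v$outcome %in% c("pass", "fail", "not_applicable"))
    expect_true(nzchar(v$fired_node))
  }
  expect_equal(ttc_evaluate(NA, "III", exposure = 5,
                            exposure_unit = "ug_per_person_day")$outcome,
               "not_applicable")
})

test_that("threshold configuration is validated", {
  expect_error(ttc_thresholds(cramer = c(I = 90, II = 540, III = 1800)),
               "I >= II >= III")
  expect_error(ttc_thresholds(organophosphate = -1), "positive")
  cfg <- ttc_thresholds(cramer = c(I = 1000, II = 500, III = 45))
  v <- ttc_evaluate("c1ccccc1", "III", exposure = 60,
                    exposure_unit = "ug_per_person_day", config = cfg)
  expect_equal(v$outcome, "fail")
})
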