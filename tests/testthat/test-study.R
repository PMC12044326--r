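# Study design validation and trial orchestration properties.

test_that("a runnable design yields an empty validation report", {
  des <- victim_ddi_design("itraconazole", 200)
  expect_length(validate_study(des), 0)
})

test_that("validation reports unresolved refs and regimen inconsistencies", {
  des <- victim_ddi_design("itraconazole", 200)
  des$perpetrator$compound <- "not-a-drug"
  expect_match(validate_study(des), "unresolved perpetrator", all = FALSE)
  des2 <- victim_ddi_design("itraconazole", 200)
  des2$perpetrator$victim_dose_day <- 99
  expect_match(validate_study(des2), "outside perpetrator regimen", all = FALSE)
  des3 <- victim_ddi_design("itraconazole", 200)
  des3$victim$dose <- -1
  expect_match(validate_study(des3), "dose", all = FALSE)
})

test_that("an interaction-free perpetrator gives GMR exactly 1 for every metric", {
  dummy <- pbpk_compound(
    name = "inert", mw = 300, bp_ratio = 1, fu_plasma = 0.5,
    absorption = list(model = "first_order", ka = 1, fa = 0.9, fu_gut = 1,
                      qgut = 10),
    distribution = list(model = "minimal_pbpk", vss = 1),
    elimination = list(cl_add = 5, cl_renal = 0))
  des <- study_design(
    victim = list(compound = "soticlestat", dose = 300),
    perpetrator = list(compound = "inert", dose = 100, interval = 24,
                       n_doses = 16, victim_dose_day = 15),
    population = small_pop(2), followup = 72)
  res <- run_ddi_study(des, compounds = list(inert = dummy), seed = 5)
  expect_identical(unname(res$gmr_auc[c("gmr", "lo", "hi")]), c(1, 1, 1))
  expect_identical(unname(res$gmr_cmax[c("gmr", "lo", "hi")]), c(1, 1, 1))
})

test_that("study results are seed-reproducible and CIs bracket the estimate", {
  des <- perp_ddi_design("midazolam", 5, n = 2, followup = 48)
  a <- run_ddi_study(des, seed = 21)
  b <- run_ddi_study(des, seed = 21)
  expect_identical(a$metrics, b$metrics)
  expect_lte(a$gmr_auc[["lo"]], a$gmr_auc[["gmr"]])
  expect_gte(a$gmr_auc[["hi"]], a$gmr_auc[["gmr"]])
  expect_gt(a$gmr_auc[["gmr"]], 0)
})

test_that("ki sensitivity scan: fold 1 equals the baseline study", {
  des <- perp_ddi_design("midazolam", 5, n = 1, followup = 48)
  base <- run_ddi_study(des, seed = 2)
  sc <- ki_sensitivity_scan(des, "CYP3A4", folds = c(1, 10), seed = 2)
  expect_equal(sc$gmr_auc[1], unname(base$gmr_auc["gmr"]), tolerance = 1e-10)
  # GMR is nonincreasing in ki_u for a pure inhibitor
  expect_gte(sc$gmr_auc[2], sc$gmr_auc[1])
})

test_that("mechanistic static ratio: limits and bounding behaviour", {
  expect_equal(mechanistic_static_aucr(list(CYP3A4 = 0.1))$aucr, 1)
  # complete hepatic inhibition of a 10% pathway: 1/0.9
  r <- mechanistic_static_aucr(list(CYP3A4 = 0.1), f_hepatic = c(CYP3A4 = 0))
  expect_equal(r$aucr, 1 / 0.9)
  # pure induction drives the ratio below 1
  r2 <- mechanistic_static_aucr(list(CYP3A4 = 0.5), f_hepatic = c(CYP3A4 = 5))
  expect_lt(r2$aucr, 1)
  expect_equal(r_value(0, 10), 1)
  expect_equal(r_value(5, 10, 0.5), 2)
})
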