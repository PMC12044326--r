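# Closed-form derivations: permeability calibration, absorption prediction,
# Michaelis-Menten clearance, Qgut availability, well-stirred model and the
# retrograde/forward round trip.

sys <- default_system()
cal2 <- data.frame(name = c("atenolol", "propranolol"),
                   papp = c(0.542, 27.8), peff_ref = c(0.20, 4.30))

test_that("Caco-2 calibration reproduces the reference compound's Peff", {
  expect_equal(predict_peff(23.4, cal2), 3.76, tolerance = 0.01)
  # calibration fixed point: a compound at a calibrator's Papp maps onto its
  # reference Peff
  expect_equal(predict_peff(0.542, cal2), 0.20, tolerance = 1e-10)
  expect_equal(predict_peff(27.8, cal2), 4.30, tolerance = 1e-10)
  # monotone: doubling Papp never decreases Peff
  grid <- 10^seq(-1, 2, length.out = 25)
  p <- vapply(grid, predict_peff, numeric(1), calibrators = cal2)
  expect_true(all(diff(p) > 0))
  expect_error(predict_peff(10, NULL), "calibrators")
})

test_that("ka/fa prediction matches the reference absorption estimates", {
  kafa <- predict_ka_fa(3.76, sys)
  expect_equal(kafa$ka, 1.64, tolerance = 0.01)
  expect_equal(kafa$fa, 0.98, tolerance = 0.005)
  # limits and monotonicity
  lim <- predict_ka_fa(1e-10, sys)
  expect_lt(lim$fa, 1e-6)
  expect_lt(lim$ka, 1e-6)
  fa_grid <- vapply(seq(0.1, 10, length.out = 30),
                    function(p) predict_ka_fa(p, sys)$fa, numeric(1))
  expect_true(all(diff(fa_grid) > 0))
})

test_that("Michaelis-Menten clearance reproduces the published linear values", {
  expect_equal(mm_clint(20.345, 5), 4.069)
  expect_equal(mm_clint(2.78, 5), 0.556)
  # half-saturation: cu = km halves the linear-region value
  expect_equal(mm_clint(20.345, 5, cu = 5), 4.069 / 2)
  cu <- seq(0, 50, by = 5)
  expect_true(all(diff(mm_clint(150, 5, cu)) < 0))
})

test_that("well-stirred model limits and linear regime", {
  expect_equal(well_stirred_cl(0, 0.1, 90), 0)
  expect_equal(well_stirred_cl(1e12, 0.1, 90), 90, tolerance = 1e-6)
  # series expansion: cl ~ fu_b * clu when fu_b*clu <= q/100
  q <- 90; fu <- 0.05; clu <- q / 100 / fu
  expect_equal(well_stirred_cl(clu, fu, q), fu * clu, tolerance = 0.01)
})

test_that("Qgut availability limits and monotonicity", {
  expect_equal(fg_qgut(2.5, 1, 0), 1)
  expect_equal(fg_qgut(2.5, 1, 2.5), 0.5)
  fg <- vapply(seq(0, 50, 2), function(cl) fg_qgut(2.5, 1, cl), numeric(1))
  expect_true(all(diff(fg) < 0))
})

test_that("retrograde derivation reproduces the published per-isoform values", {
  fub <- fu_blood(0.066, 0.6866)
  ts <- list(UserUGT1 = list(liver = 0, intestine = 1, kidney = 0))
  rg <- retrograde_clint(28.7, 0.22, fub,
                         list(UGT2B4 = 0.8, UGT1A9 = 0.1, CYP3A4 = 0.1),
                         sys, bp_ratio = 0.6866, tissue_scalars = ts)
  expect_equal(unname(rg$per_enzyme_clu_int["UGT2B4"]), 4.069, tolerance = 0.10)
  expect_equal(unname(rg$per_enzyme_clu_int["UGT1A9"]), 0.556, tolerance = 0.10)
  expect_equal(unname(rg$per_enzyme_clu_int["CYP3A4"]), 0.161, tolerance = 0.10)
  # forward recomputation returns the net metabolic clearance to 1e-8
  fwd <- forward_metabolic_cl(rg$per_enzyme_clu_int, fub, sys, ts)
  expect_equal(fwd, (28.7 - 0.22) / 0.6866, tolerance = 1e-8)
  # a single-enzyme split carries the whole hepatic intrinsic clearance
  rg1 <- retrograde_clint(28.7, 0.22, fub, list(CYP3A4 = 1), sys,
                          bp_ratio = 0.6866)
  expect_equal(sum(rg1$per_enzyme_clu_int > 0), 1L)
  expect_equal(rg1$clu_int_renal, 0)
})

test_that("forward and retrograde are mutual inverses over a parameter sweep", {
  set.seed(42)
  fub <- fu_blood(0.066, 0.6866)
  for (i in 1:20) {
    cl <- runif(1, 1, 60)
    fm <- c(UGT2B4 = runif(1), UGT1A9 = runif(1), CYP3A4 = runif(1))
    fm <- fm / sum(fm)
    rg <- retrograde_clint(cl, 0, fub, as.list(fm), sys, bp_ratio = 0.6866)
    fwd <- forward_metabolic_cl(rg$per_enzyme_clu_int, fub, sys)
    expect_equal(fwd, cl / 0.6866, tolerance = 1e-8)
  }
  # model cannot represent metabolic clearance at/above organ blood flow
  expect_error(retrograde_clint(200, 0, fub, list(CYP3A4 = 1), sys),
               "cannot represent")
})

test_that("unit chain from µL/min/pmol to L/h multiplies through", {
  # 1 µL/min/pmol over a 1e6 pmol pool = 1e6 µL/min = 1 L/min = 60 L/h
  c_e <- 1; pool <- 1e6
  expect_equal(c_e * pool * pbpkddi:::UL_MIN_TO_L_H, 60)
})
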