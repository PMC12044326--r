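# Compound schema: fixture fidelity, invariant enforcement, lossless I/O.

test_that("packaged reference compound carries the published parameter set", {
  soti <- builtin_compound("soticlestat")
  expect_equal(soti$fu_plasma, 0.066)
  expect_equal(soti$bp_ratio, 0.6866)
  expect_equal(soti$mw, 373.45)
  expect_equal(soti$elimination$cl_iv, 28.7)
  expect_equal(soti$elimination$cl_renal, 0.22)
  expect_equal(unlist(soti$elimination$fm),
               c(UGT2B4 = 0.8, UGT1A9 = 0.1, CYP3A4 = 0.1))
  expect_equal(soti$elimination$mm$UGT2B4$vmax, 20.345)
  expect_equal(soti$elimination$mm$UGT2B4$km, 5)
  expect_equal(soti$interaction$ki$`P-gp`$ki, 80)
  expect_equal(soti$interaction$ki$CYP3A4$ki, 12.4)
  expect_equal(soti$interaction$ki$CYP3A4$fu_mic, 0.94)
  expect_equal(soti$distribution$vss, 0.36)
  expect_equal(soti$distribution$v_sac, 0.234)
})

test_that("fm sum, unknown keys/enzymes and stored ki_u are rejected", {
  soti <- builtin_compound("soticlestat")
  bad <- unclass(soti)
  bad$elimination$fm$UGT2B4 <- 1.1
  expect_error(validate_compound(bad), "fm values sum")

  bad2 <- unclass(soti)
  bad2$absorption$kaa <- 1
  expect_error(validate_compound(bad2), "unknown key")

  bad3 <- unclass(soti)
  bad3$elimination$fm$CYP9Z9 <- 0
  expect_error(validate_compound(bad3), "unknown enzyme")

  bad4 <- unclass(soti)
  bad4$interaction$ki$CYP3A4$ki_u <- 11.656
  expect_error(validate_compound(bad4), "derived, never stored")

  bad5 <- unclass(soti)
  bad5$fu_plasma <- NULL
  expect_error(validate_compound(bad5), "fu_plasma")
})

test_that("save/load round trip is lossless to full precision", {
  soti <- builtin_compound("soticlestat")
  path <- tempfile(fileext = ".yaml")
  write_compound(soti, path)
  back <- load_compound(path)
  expect_identical(unclass(back), unclass(soti))
})

test_that("every library entry loads and validates", {
  for (nm in compound_library()) {
    expect_s3_class(builtin_compound(nm), "pbpk_compound")
  }
  expect_error(builtin_compound("unknown_drug"), "unknown library compound")
})

test_that("enzyme names used by any compound are covered by system abundances", {
  sys <- default_system()
  for (nm in compound_library()) {
    cmp <- builtin_compound(nm)
    el <- cmp$elimination
    enz <- unique(c(names(el$fm), names(el$clint), names(el$mm)))
    for (e in enz) expect_false(is.null(sys$abundance[[e]]),
                                label = paste(nm, e))
  }
})
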