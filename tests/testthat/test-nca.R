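# Non-compartmental analysis and GMR statistics against closed-form oracles.

test_that("mono-exponential profile recovers lambda_z and AUC0-inf", {
  prof <- synth_profile(coefs = 100, rates = 0.1, times = seq(0, 48, 1))
  m <- nca(prof)
  expect_equal(m$lambda_z, 0.1, tolerance = 1e-3)
  expect_equal(m$auc_0_inf, 1000, tolerance = 0.005)
  expect_equal(m$cmax, 100)
  expect_lt(m$extrap_pct, 100 * exp(-0.1 * 48) + 1)
})

test_that("bi-exponential profile matches the analytic A/alpha + B/beta", {
  A <- 80; B <- 20; al <- 0.6; be <- 0.05
  prof <- synth_profile(coefs = c(A, B), rates = c(al, be),
                        times = c(seq(0, 12, 0.5), seq(13, 96, 1)))
  m <- nca(prof)
  expect_equal(m$auc_0_inf, A / al + B / be, tolerance = 0.005)
  expect_equal(m$lambda_z, be, tolerance = 0.01)
})

test_that("degenerate profiles are flagged rather than mis-analyzed", {
  z <- nca(list(time = 0:10, conc = rep(0, 11)))
  expect_equal(z$cmax, 0)
  expect_true(length(z$flags) > 0)
  # too few terminal points for a slope
  short <- nca(list(time = c(0, 1, 2), conc = c(0, 10, 12)))
  expect_true(is.na(short$auc_0_inf))
})

test_that("NCA is invariant to interior sampling refinement on a smooth profile", {
  t1 <- c(seq(0, 12, 0.25), seq(12.5, 72, 0.5))
  t2 <- sort(unique(c(t1, t1[-1] - 0.125)))
  m1 <- nca(synth_profile(c(-120, 120), c(1.2, 0.08), times = t1))
  m2 <- nca(synth_profile(c(-120, 120), c(1.2, 0.08), times = t2))
  expect_equal(m1$auc_0_inf, m2$auc_0_inf, tolerance = 0.002)
})

test_that("GMR point estimate and CI match direct log-space arithmetic", {
  expect_equal(unname(gmr(c(2, 3, 4), c(2, 3, 4))[1:3]), c(1, 1, 1))
  expect_equal(unname(gmr(c(2, 0.5), c(1, 1))["gmr"]), 1)
  r <- c(1.2, 1.3, 1.4, 1.35)
  test <- r * 10; ref <- rep(10, 4)
  lr <- log(r)
  half <- qt(0.95, 3) * sd(lr) / 2
  expect_equal(unname(gmr(test, ref)["gmr"]), exp(mean(lr)), tolerance = 1e-10)
  expect_equal(unname(gmr(test, ref)["lo"]), exp(mean(lr) - half), tolerance = 1e-10)
  expect_equal(unname(gmr(test, ref)["hi"]), exp(mean(lr) + half), tolerance = 1e-10)
  expect_error(gmr(1:3, 1:4), "unpaired")
})

test_that("synthetic profiles are reproducible and carry exact truths", {
  a <- synth_profile(100, 0.1, cv = 0.05, seed = 3)
  b <- synth_profile(100, 0.1, cv = 0.05, seed = 3)
  expect_identical(a$conc, b$conc)
  expect_equal(a$truth$auc_0_inf, 1000)
  # with 5% noise at dense sampling, NCA recovers truth within 3%
  noisy <- synth_profile(100, 0.1, times = seq(0, 60, 0.5), cv = 0.05, seed = 9)
  m <- nca(noisy)
  expect_lt(abs(m$auc_0_inf / 1000 - 1), 0.03)
})
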