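# Dynamic engine: closed-form limits, mass conservation, integrator
# robustness, interaction primitives, dose superposition, engine equivalence.

test_that("zero dose gives an identically zero profile (and fails validation)", {
  des <- study_design(victim = list(compound = "soticlestat", dose = 300),
                      followup = 24)
  ind <- mean_individual()
  des0 <- des
  des0$victim$dose <- 0
  sim <- simulate_pk("soticlestat", des0, ind)
  expect_true(all(sim$victim$conc == 0))
  expect_error(run_ddi_study(des0, seed = 1), "dose")
})

test_that("linear special case matches the one-compartment closed form", {
  cmp <- linear_test_compound(clint = 0.5, vss = 0.5, ka = 1.0)
  ind <- fast_transit_individual()
  des <- study_design(victim = list(compound = cmp, dose = 100), followup = 24)
  sim <- simulate_pk(cmp, des, ind)
  # expected first-order elimination rate from the well-stirred limit
  pools <- pbpkddi:::enzyme_pools(ind$system)
  clu <- 0.5 * pools$liver[["CYP3A4"]] * pbpkddi:::UL_MIN_TO_L_H
  cl <- well_stirred_cl(clu, 0.1, ind$system$q_hepatic)
  v <- 0.5 * 70
  k <- cl / v
  tt <- sim$victim$time
  pred <- 100 * 1.0 / (v * (1.0 - k)) * (exp(-k * tt) - exp(-1.0 * tt)) * 1000
  obs <- sim$victim$conc
  keep <- pred > max(pred) * 1e-3
  expect_lt(max(abs(obs[keep] - pred[keep]) / max(pred)), 1e-3)
})

test_that("mass balance holds and the solution is tolerance-converged", {
  des <- study_design(victim = list(compound = "soticlestat", dose = 300),
                      followup = 96)
  ind <- mean_individual()
  sim <- simulate_pk("soticlestat", des, ind)
  expect_lt(sim$victim$mass_balance_rel_err, 1e-3)
  auc <- function(p) sum(diff(p$time) * (head(p$conc, -1) + tail(p$conc, -1)) / 2)
  sim2 <- simulate_pk("soticlestat", des, ind, rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(auc(sim2$victim) / auc(sim$victim) - 1), 1e-4)
})

test_that("dose superposition holds linearly and fails upward under MM", {
  ind <- mean_individual()
  auc <- function(p) sum(diff(p$time) * (head(p$conc, -1) + tail(p$conc, -1)) / 2)
  # linear compound: double dose -> exactly double AUC
  cmp <- linear_test_compound()
  a1 <- auc(simulate_pk(cmp, study_design(victim = list(compound = cmp, dose = 50),
                                          followup = 48), ind)$victim)
  a2 <- auc(simulate_pk(cmp, study_design(victim = list(compound = cmp, dose = 100),
                                          followup = 48), ind)$victim)
  expect_equal(a2 / a1, 2, tolerance = 1e-6)
  # saturable gut glucuronidation: doubling the dose more than doubles AUC
  s1 <- auc(simulate_pk("soticlestat",
                        study_design(victim = list(compound = "soticlestat",
                                                   dose = 300), followup = 96),
                        ind)$victim)
  s2 <- auc(simulate_pk("soticlestat",
                        study_design(victim = list(compound = "soticlestat",
                                                   dose = 600), followup = 96),
                        ind)$victim)
  expect_gt(s2 / s1, 2.05)
})

test_that("an interactionless perpetrator reproduces the victim-alone profile bit for bit", {
  ind <- mean_individual()
  dummy <- pbpk_compound(
    name = "inert", mw = 300, bp_ratio = 1, fu_plasma = 0.5,
    absorption = list(model = "first_order", ka = 1, fa = 0.9, fu_gut = 1,
                      qgut = 10),
    distribution = list(model = "minimal_pbpk", vss = 1),
    elimination = list(cl_add = 5, cl_renal = 0))
  des_alone <- study_design(victim = list(compound = "soticlestat", dose = 300),
                            followup = 96)
  des_co <- study_design(
    victim = list(compound = "soticlestat", dose = 300),
    perpetrator = list(compound = dummy, dose = 100, interval = 24,
                       n_doses = 16, victim_dose_day = 15),
    followup = 96)
  alone <- simulate_pk("soticlestat", des_alone, ind)
  co <- simulate_pk("soticlestat", des_co, ind, perpetrator = dummy)
  expect_identical(alone$victim$conc, co$victim$conc)
  expect_s3_class(co$perpetrator, "pbpk_profile")
})

test_that("inhibition factor limits and arithmetic", {
  expect_equal(inhibition_factor(0, 12.4, 0.94), 1)
  kiu <- 12.4 * 0.94
  expect_equal(inhibition_factor(kiu, 12.4, 0.94), 0.5)
  expect_equal(inhibition_factor(1.1656, 12.4, 0.94), 1 / 1.1, tolerance = 1e-12)
  cu <- seq(0, 50, 5)
  expect_true(all(diff(inhibition_factor(cu, 10)) < 0))
})

test_that("induction rate law: steady states and washout kinetics", {
  expect_equal(induction_rate(1, 1, 0.03, 8, 0.32, cu = 0), 0)
  # constant cu = c50: steady state at fold 1 + ind_max/2
  fold <- 1 + 8 / 2
  expect_equal(induction_rate(fold, 1, 0.03, 8, 0.32, cu = 0.32), 0)
  # washout from induced steady state decays with rate kdeg (closed form)
  kdeg <- 0.05; e0 <- 1; e_start <- 4
  tt <- seq(0, 60, 1)
  analytic <- e0 + (e_start - e0) * exp(-kdeg * tt)
  e <- e_start; dt <- 0.01
  num <- numeric(length(tt)); num[1] <- e
  for (i in seq(2, length(tt))) {
    for (s in seq_len(1 / dt)) e <- e + dt * induction_rate(e, e0, kdeg, 8, 0.32, cu = 0)
    num[i] <- e
  }
  expect_lt(max(abs(num - analytic)), 1e-3)
})

test_that("compiled and pure-R right-hand sides agree", {
  ind <- mean_individual()
  des <- victim_ddi_design("itraconazole", 200, followup = 48)
  a <- simulate_pk("soticlestat", des, ind, engine = "compiled")
  b <- simulate_pk("soticlestat", des, ind, engine = "R")
  expect_lt(max(abs(a$victim$conc - b$victim$conc)) / max(b$victim$conc), 1e-8)
  expect_lt(max(abs(a$perpetrator$conc - b$perpetrator$conc)) /
              max(b$perpetrator$conc), 1e-8)
})

test_that("profiles are reported on the requested observation window", {
  des <- victim_ddi_design("fluconazole", 200, followup = 48)
  sim <- simulate_pk("soticlestat", des, mean_individual())
  expect_equal(min(sim$victim$time), 0)
  expect_equal(max(sim$victim$time), 48)
  expect_true(all(diff(sim$victim$time) > 0))
  expect_true(all(sim$victim$conc >= 0))
})
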